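# Internal numeric helpers shared across the pipeline.

# Round-half-up to nearest integer. Applied after every floating-point pixel
# computation so results do not depend on banker's rounding of round().
roundHalfUp <- function(x) floor(x + 0.5)

clamp255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# Assert an object is a usable grayscale image matrix.
checkGrayImage <- function(img, minDim = 1L, what = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix of intensities")
  if (anyNA(img)) stop(what, " contains NA")
  if (any(img < 0) || any(img > 255))
    stop(what, " intensities must lie in [0, 255]")
  if (nrow(img) < minDim || ncol(img) < minDim)
    stop(what, sprintf(" must be at least %d x %d", minDim, minDim))
  invisible(img)
}

# Deterministic seed derivation: every class/sample seed flows from the
# master seed through a small multiplicative-congruential mix. Multiplier
# 69069 keeps every intermediate product below 2^48, exactly representable
# in doubles, so the chain is platform independent; results stay in
# [0, 2^31 - 2], valid set.seed() input.
deriveSeed <- function(master, ...) {
  h <- as.double(master %% 2147483647)
  for (k in c(...)) {
    h <- (h * 69069 + as.double(k %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

# Run expr with a private RNG state so library calls never disturb the
# caller's random stream.
withSeed <- function(seed, expr) {
  hasOld <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasOld) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasOld) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
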