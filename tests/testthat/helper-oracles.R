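# Independent reference implementations and fixture builders used across
# the suite. The oracles deliberately avoid the package's vectorized code
# paths: nested loops, atan() with explicit sign cases instead of atan2,
# exhaustive enumeration instead of the sweep.

# Naive per-pixel code-map reference. Angle of (vv, vh) from atan() plus a
# sign-case table, mapped to [0, 2*pi], quantized by nearest sector.
naiveCodeMap <- function(img, variant = "00", T = 8L) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_integer_, h - 2L, w - 2L)
  for (i in 2:(h - 1)) {
    for (j in 2:(w - 1)) {
      if (variant == "00") {
        vv <- img[i, j + 1] - img[i, j - 1]
        vh <- img[i - 1, j] - img[i + 1, j]
      } else {
        vv <- img[i - 1, j + 1] - img[i + 1, j - 1]
        vh <- img[i + 1, j + 1] - img[i - 1, j - 1]
      }
      phi <- if (vv == 0 && vh == 0) 0
        else if (vv == 0) sign(vh) * pi / 2
        else if (vv > 0) atan(vh / vv)
        else if (vh >= 0) atan(vh / vv) + pi
        else atan(vh / vv) - pi
      tp <- phi + pi
      out[i - 1L, j - 1L] <- as.integer(floor(tp / (2 * pi / T) + 0.5) %% T)
    }
  }
  out
}

# Hand-coded 3x3 Sobel loops for the ROI oracle: returns the bounding box
# of above-threshold responses per direction.
naiveSobelBox <- function(img, frac = 0.25) {
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  mx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # columns of the mask
  for (i in 2:(h - 1)) {
    for (j in 2:(w - 1)) {
      win <- img[(i - 1):(i + 1), (j - 1):(j + 1)]
      gx[i, j] <- sum(win * mx)
      gy[i, j] <- sum(win * t(mx))
    }
  }
  cols <- which(apply(abs(gx) >= frac * max(abs(gx)), 2, any))
  rows <- which(apply(abs(gy) >= frac * max(abs(gy)), 1, any))
  list(minRow = min(rows), maxRow = max(rows),
       minCol = min(cols), maxCol = max(cols))
}

# Exhaustive verification-metrics reference: enumerate every candidate
# threshold, locate the FAR/FRR crossing by scanning.
enumRocEER <- function(genuine, imposter) {
  thr <- sort(unique(c(genuine, imposter)))
  thr <- c(thr, max(thr) + 1)
  far <- vapply(thr, function(t) mean(imposter >= t), 1)
  frr <- vapply(thr, function(t) mean(genuine < t), 1)
  d <- far - frr
  k <- which(d <= 0)[1]
  if (d[k] == 0) far[k]
  else {
    a <- d[k - 1] / (d[k - 1] - d[k])
    far[k - 1] + a * (far[k] - far[k - 1])
  }
}

# 90-degree counter-clockwise rotation of a matrix.
rotCCW <- function(m) {
  r <- t(m)
  r[nrow(r):1, , drop = FALSE]
}

# Smooth integer test image: mixture of random low-frequency sinusoids
# with strong gradients, so zero-gradient pairs are rare; fixtures with
# any zero pair are regenerated.
makeSmoothImage <- function(seed, h = 24L, w = 24L) {
  set.seed(seed)
  for (try in 1:50) {
    x <- matrix(rep(seq_len(w), each = h), h, w)
    y <- matrix(rep(seq_len(h), times = w), h, w)
    f <- matrix(0, h, w)
    for (k in 1:3) {
      f <- f + runif(1, 0.5, 1) *
        sin(2 * pi * (runif(1, 0.04, 0.15) * x + runif(1, 0.04, 0.15) * y +
                        runif(1)))
    }
    img <- floor((f - min(f)) / (max(f) - min(f)) * 255 + 0.5)
    ic <- 2:(h - 1); jc <- 2:(w - 1)
    zeroPair <- (img[ic, jc + 1] == img[ic, jc - 1]) &
                (img[ic - 1, jc] == img[ic + 1, jc])
    zeroPair45 <- (img[ic - 1, jc + 1] == img[ic + 1, jc - 1]) &
                  (img[ic + 1, jc + 1] == img[ic - 1, jc - 1])
    if (!any(zeroPair) && !any(zeroPair45)) return(img)
  }
  stop("could not build a zero-pair-free smooth fixture")
}

# Random 8-bit image.
makeRandomImage <- function(seed, h, w) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# Small deterministic database config for protocol tests.
toyConfig <- function(nClasses = 5L, nSamples = 4L, seed = 11L, ...) {
  syntheticConfig(nClasses = nClasses, nSamples = nSamples,
                  masterSeed = seed, ...)
}
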