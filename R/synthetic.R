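# Seeded synthetic vein-image generator. Each class is a fixed network of
# smooth dark curves (spline vessels) on a brighter background; each sample
# is a perturbed capture of its class pattern: sub-pixel translation,
# brightness scale, Gaussian blur, additive noise. All randomness flows
# from one master seed through per-class / per-sample derived seeds, so any
# subset of the database is reproducible independently.

#' Build a synthetic generator configuration
#'
#' Defaults describe the package's reference study conditions: 40 classes
#' of 12 samples rendered directly at the post-ROI size 96 x 64, vessel
#' networks of 3-7 strokes of width 2-6 px and contrast 60-120 below a
#' background of about 180, per-sample jitter up to +/-2 px, brightness
#' scale +/-5 percent, blur sigma 1.5 px and noise sigma 8. Full-frame
#' mode renders a 320 x 240 capture with a dark border around a bright
#' finger band, to exercise ROI detection.
#'
#' @param nClasses,nSamples database shape.
#' @param imageWidth,imageHeight canvas size; defaults depend on
#'   `fullFrame`.
#' @param fullFrame render the raw-capture geometry instead of the
#'   post-ROI crop.
#' @param nVesselRange,vesselWidthRange,vesselContrastRange per-vessel
#'   draw ranges (count, stroke width in px, intensity drop).
#' @param jitterMax,brightnessRange,blurSigma,noiseSigma per-sample
#'   perturbation magnitudes.
#' @param masterSeed integer master seed.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nClasses = 40L, nSamples = 12L,
                            imageWidth = if (fullFrame) 320L else 96L,
                            imageHeight = if (fullFrame) 240L else 64L,
                            fullFrame = FALSE,
                            nVesselRange = c(3L, 7L),
                            vesselWidthRange = c(2, 6),
                            vesselContrastRange = c(60, 120),
                            jitterMax = 2,
                            brightnessRange = 0.05,
                            blurSigma = 1.5,
                            noiseSigma = 8,
                            masterSeed = 1L) {
  new("SyntheticConfig",
      nClasses = as.integer(nClasses), nSamples = as.integer(nSamples),
      imageWidth = as.integer(imageWidth),
      imageHeight = as.integer(imageHeight),
      fullFrame = isTRUE(fullFrame),
      nVesselRange = as.integer(nVesselRange),
      vesselWidthRange = as.numeric(vesselWidthRange),
      vesselContrastRange = as.numeric(vesselContrastRange),
      jitterMax = as.numeric(jitterMax),
      brightnessRange = as.numeric(brightnessRange),
      blurSigma = as.numeric(blurSigma),
      noiseSigma = as.numeric(noiseSigma),
      masterSeed = as.integer(masterSeed))
}

#' Generate the vessel network of one class
#'
#' A deterministic set of smooth random curves in unit coordinates: each
#' vessel is a natural spline through control points whose x positions
#' span the image and whose y positions follow a damped random walk. Width
#' and contrast are drawn per vessel from the configured ranges. The same
#' class seed always yields the identical curve set.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param classIndex 1-based class number; the class seed is derived from
#'   `masterSeed` and this index.
#' @return list of vessels, each with `ctrlX`, `ctrlY` (unit coordinates),
#'   `width` (px) and `contrast` (intensity units); attribute `seed`
#'   records the derived class seed.
#' @export
generateClassPattern <- function(cfg, classIndex) {
  stopifnot(is(cfg, "SyntheticConfig"), classIndex >= 1L)
  seed <- deriveSeed(cfg@masterSeed, 1L, classIndex)
  vessels <- withSeed(seed, {
    nv <- sample(cfg@nVesselRange[1]:cfg@nVesselRange[2], 1L)
    lapply(seq_len(nv), function(v) {
      nCtrl <- 6L
      ctrlX <- seq(-0.05, 1.05, length.out = nCtrl)
      y0 <- stats::runif(1, 0.12, 0.88)
      steps <- stats::rnorm(nCtrl - 1L, 0, 0.10)
      ctrlY <- pmin(0.95, pmax(0.05, y0 + cumsum(c(0, steps))))
      list(ctrlX = ctrlX, ctrlY = ctrlY,
           width = stats::runif(1, cfg@vesselWidthRange[1],
                                cfg@vesselWidthRange[2]),
           contrast = stats::runif(1, cfg@vesselContrastRange[1],
                                   cfg@vesselContrastRange[2]))
    })
  })
  attr(vessels, "seed") <- seed
  vessels
}

# Separable Gaussian blur via row-normalized band matrices; truncation at
# 3 sigma, edge weights renormalized (replicate-like behavior without
# explicit padding).
.blurKernelCache <- new.env(parent = emptyenv())

gaussianBlurMatrix <- function(n, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  if (!is.null(.blurKernelCache[[key]])) return(.blurKernelCache[[key]])
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-d^2 / (2 * sigma^2))
  K[d > ceiling(3 * sigma)] <- 0
  K <- K / rowSums(K)
  .blurKernelCache[[key]] <- K
  K
}

gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  Kr <- gaussianBlurMatrix(nrow(img), sigma)
  Kc <- gaussianBlurMatrix(ncol(img), sigma)
  Kr %*% img %*% t(Kc)
}

# Rasterize one vessel into an intensity-drop canvas. The curve is a
# function y(x) evaluated per pixel column; the stroke profile has a small
# flat core plus a Gaussian skirt whose sigma equals the vessel half-width,
# mimicking the diffuse appearance of subdermal vessels under NIR
# transillumination (light scattering spreads the absorption shadow in
# proportion to vessel caliber). The smooth profile also anti-aliases the
# stroke: the descriptor operates on gradients and a hard binary edge
# would create spurious codes.
.rasterVessel <- function(vessel, rows, cols, region, dx, dy) {
  h <- region$h; w <- region$w
  fy <- stats::splinefun(vessel$ctrlX, vessel$ctrlY, method = "natural")
  # jitter is expressed in post-ROI pixel units; scale to region size
  sc <- region$h / 64
  xu <- (cols - region$col0 + dx * sc) / (w - 1)
  yc <- region$row0 + fy(xu) * (h - 1) + dy * sc
  halfw <- vessel$width * sc / 2
  dist <- abs(outer(rows, yc, "-"))
  excess <- pmax(0, dist - pmax(0.5, halfw / 2))
  vessel$contrast * exp(-excess^2 / (2 * halfw^2))
}

#' Render one sample of a class pattern
#'
#' Rasterizes the class's vessels (anti-aliased spline strokes, intensity
#' drop below a background of 180), then applies the per-sample seeded
#' perturbations: sub-pixel translation within `jitterMax`, global
#' brightness scale, Gaussian blur, additive Gaussian noise, clamp to
#' `[0, 255]` and round. In full-frame mode the vessels live in a bright
#' finger band over a dark border.
#'
#' @param pattern output of [generateClassPattern()].
#' @param cfg a [SyntheticConfig-class].
#' @param classIndex,sampleIndex position in the database; the sample seed
#'   is derived from the master seed and both indices.
#' @return integer grayscale matrix `imageHeight x imageWidth`.
#' @export
renderSample <- function(pattern, cfg, classIndex, sampleIndex) {
  stopifnot(is(cfg, "SyntheticConfig"))
  seed <- deriveSeed(cfg@masterSeed, 2L, classIndex, sampleIndex)
  h <- cfg@imageHeight; w <- cfg@imageWidth
  withSeed(seed, {
    dx <- stats::runif(1, -cfg@jitterMax, cfg@jitterMax)
    dy <- stats::runif(1, -cfg@jitterMax, cfg@jitterMax)
    bright <- stats::runif(1, 1 - cfg@brightnessRange,
                           1 + cfg@brightnessRange)
    if (cfg@fullFrame) {
      # bright finger band with soft edges over a dark border
      m <- list(row = max(3L, round(0.18 * h)), col = max(3L, round(0.05 * w)))
      region <- list(row0 = m$row + 1, col0 = m$col + 1,
                     h = h - 2 * m$row, w = w - 2 * m$col)
      canvas <- matrix(15, h, w)
      canvas[(m$row + 1):(h - m$row), (m$col + 1):(w - m$col)] <- 180
    } else {
      region <- list(row0 = 1, col0 = 1, h = h, w = w)
      canvas <- matrix(180, h, w)
    }
    rows <- seq_len(h)
    cols <- seq_len(w)
    drop <- matrix(0, h, w)
    for (v in pattern) drop <- drop + .rasterVessel(v, rows, cols, region,
                                                    dx, dy)
    if (cfg@fullFrame) {
      # vessels exist only inside the finger band
      mask <- matrix(0, h, w)
      mask[(region$row0):(region$row0 + region$h - 1),
           (region$col0):(region$col0 + region$w - 1)] <- 1
      drop <- drop * mask
    }
    img <- (canvas - pmin(drop, 170)) * bright
    img <- gaussianBlur(img, cfg@blurSigma)
    if (cfg@noiseSigma > 0)
      img <- img + stats::rnorm(length(img), 0, cfg@noiseSigma)
    out <- clamp255(roundHalfUp(img))
    storage.mode(out) <- "integer"
    out
  })
}

#' Generate a complete synthetic database
#'
#' Builds `nClasses x nSamples` images from the configuration. With `dir`
#' given, the database is also written in the evaluation layout
#' `<dir>/<class_id>/<NN>.pgm` together with a `manifest.json` recording
#' the configuration and every derived seed; running the same
#' configuration twice produces byte-identical trees.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param dir optional output directory.
#' @return a [VeinDatabase-class] (metadata records config and seeds).
#' @examples
#' db <- generateDatabase(syntheticConfig(nClasses = 3, nSamples = 2))
#' nClasses(db)
#' @export
generateDatabase <- function(cfg, dir = NULL) {
  stopifnot(is(cfg, "SyntheticConfig"))
  ids <- sprintf("class_%03d", seq_len(cfg@nClasses))
  classSeeds <- integer(cfg@nClasses)
  sampleSeeds <- vector("list", cfg@nClasses)
  samples <- vector("list", cfg@nClasses)
  for (ci in seq_len(cfg@nClasses)) {
    pattern <- generateClassPattern(cfg, ci)
    classSeeds[ci] <- attr(pattern, "seed")
    sampleSeeds[[ci]] <- vapply(seq_len(cfg@nSamples), function(si)
      deriveSeed(cfg@masterSeed, 2L, ci, si), 1L)
    samples[[ci]] <- lapply(seq_len(cfg@nSamples), function(si)
      renderSample(pattern, cfg, ci, si))
  }
  names(samples) <- ids
  cfgList <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(cfgList) <- slotNames(cfg)
  db <- new("VeinDatabase", classIds = ids, samples = samples,
            metadata = list(config = cfgList, classSeeds = classSeeds,
                            sampleSeeds = sampleSeeds))
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("destination not writable: ", dir)
    for (ci in seq_len(cfg@nClasses)) {
      cdir <- file.path(dir, ids[ci])
      dir.create(cdir, showWarnings = FALSE)
      for (si in seq_len(cfg@nSamples))
        writePGM(samples[[ci]][[si]],
                 file.path(cdir, sprintf("%02d.pgm", si)))
    }
    jsonlite::write_json(
      list(config = cfgList, classSeeds = classSeeds,
           sampleSeeds = sampleSeeds),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  db
}

#' Read a database directory
#'
#' Expects the evaluation layout `<root>/<class_id>/<sample>.{pgm,png,ppm,bmp}`;
#' sample order is the zero-padded numeric filename order.
#'
#' @param dir database root directory.
#' @return a [VeinDatabase-class].
#' @export
readDatabase <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  cls <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (!length(cls)) stop("database directory contains no class folders")
  samples <- lapply(cls, function(cid) {
    files <- list.files(file.path(dir, cid),
                        pattern = "\\.(pgm|png|ppm|bmp)$", full.names = TRUE)
    if (!length(files)) stop("class folder has no images: ", cid)
    lapply(files[order(basename(files))], readImageGray)
  })
  names(samples) <- cls
  new("VeinDatabase", classIds = cls, samples = samples,
      metadata = list(sourceDir = dir))
}
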