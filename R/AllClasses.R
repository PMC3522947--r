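#' @import methods
NULL

#' Local directional code map of one image
#'
#' A `CodeMap` holds the per-pixel orientation codes extracted from a
#' grayscale image: an integer matrix with values in `[0, T)`, one code per
#' interior pixel of the source, so its dimensions are
#' `(source height - 2) x (source width - 2)`. The neighbor convention
#' (`"00"` axis-aligned or `"45"` diagonal) and the number of dominant
#' orientations `T` travel with the codes because maps are only comparable
#' when both agree.
#'
#' @slot codes integer matrix of orientation codes, each in `[0, T)`.
#' @slot nOrientations number of dominant orientations `T` (>= 2).
#' @slot variant `"00"` or `"45"`.
#'
#' @seealso [extractCodeMap()], [matchScore()]
#' @export
setClass("CodeMap",
  representation(
    codes = "matrix",
    nOrientations = "integer",
    variant = "character"
  )
)

setValidity("CodeMap", function(object) {
  msg <- character()
  Tn <- object@nOrientations
  if (length(Tn) != 1L || is.na(Tn) || Tn < 2L)
    msg <- c(msg, "nOrientations must be a single integer >= 2")
  if (!identical(length(object@variant), 1L) ||
      !object@variant %in% c("00", "45"))
    msg <- c(msg, "variant must be \"00\" or \"45\"")
  cd <- object@codes
  if (!is.numeric(cd))
    msg <- c(msg, "codes must be a numeric/integer matrix")
  else if (length(cd) && (anyNA(cd) || any(cd < 0) || any(cd >= Tn) ||
                          any(cd != floor(cd))))
    msg <- c(msg, "codes must be integers in [0, nOrientations)")
  if (length(msg)) msg else TRUE
})

#' Result of comparing two code maps
#'
#' Per-position agreement bitmap plus the scalar similarity score: the
#' fraction of positions at which the two maps carry the same code.
#'
#' @slot bitmap logical matrix, `TRUE` where the codes agree.
#' @slot score fraction of agreeing positions, in `[0, 1]`.
#' @slot codeNum total number of compared positions.
#'
#' @seealso [matchScore()]
#' @export
setClass("MatchResult",
  representation(
    bitmap = "matrix",
    score = "numeric",
    codeNum = "integer"
  )
)

setValidity("MatchResult", function(object) {
  msg <- character()
  if (!is.logical(object@bitmap))
    msg <- c(msg, "bitmap must be a logical matrix")
  if (length(object@score) != 1L || object@score < 0 || object@score > 1)
    msg <- c(msg, "score must be a single value in [0, 1]")
  if (length(object@codeNum) != 1L ||
      object@codeNum != length(object@bitmap))
    msg <- c(msg, "codeNum must equal the number of bitmap positions")
  if (length(msg)) msg else TRUE
})

#' A database of vein image samples grouped into classes
#'
#' All samples captured from one finger form a class. Sample order within a
#' class is stable and meaningful: the evaluation protocols reference "the
#' first k samples". Samples are stored as integer grayscale matrices
#' (rows = image rows, 0-255).
#'
#' @slot classIds character vector of class identifiers.
#' @slot samples list (one element per class, named by classIds) of lists of
#'   grayscale integer matrices.
#' @slot metadata list of free-form provenance (generator config, seeds,
#'   source directory).
#'
#' @seealso [generateDatabase()], [readDatabase()], [runVerification()]
#' @export
setClass("VeinDatabase",
  representation(
    classIds = "character",
    samples = "list",
    metadata = "list"
  )
)

setValidity("VeinDatabase", function(object) {
  msg <- character()
  if (length(object@classIds) != length(object@samples))
    msg <- c(msg, "one sample list per class id required")
  if (anyDuplicated(object@classIds))
    msg <- c(msg, "class ids must be unique")
  if (any(vapply(object@samples, length, 1L) == 0L))
    msg <- c(msg, "every class must contain at least one sample")
  if (length(msg)) msg else TRUE
})

#' Verification (1:1 matching) experiment report
#'
#' Genuine and imposter score samples together with the threshold sweep:
#' for each threshold tau, FAR(tau) is the fraction of imposter scores at
#' or above tau and FRR(tau) the fraction of genuine scores below tau.
#' Summary
#' metrics: the equal error rate (EER, where FAR = FRR, linearly
#' interpolated), the FAR at the zero-FRR operating point and the FRR at
#' the zero-FAR operating point.
#'
#' @slot genuineScores numeric vector of within-class similarity scores.
#' @slot imposterScores numeric vector of cross-class similarity scores.
#' @slot roc data.frame with columns threshold, FAR, FRR.
#' @slot EER equal error rate, in `[0, 1]`.
#' @slot FARatZeroFRR minimal false accept rate with no false rejections.
#' @slot FRRatZeroFAR minimal false rejection rate with no false accepts.
#'
#' @seealso [rocMetrics()], [runVerification()]
#' @export
setClass("VerificationReport",
  representation(
    genuineScores = "numeric",
    imposterScores = "numeric",
    roc = "data.frame",
    EER = "numeric",
    FARatZeroFRR = "numeric",
    FRRatZeroFAR = "numeric"
  )
)

setValidity("VerificationReport", function(object) {
  msg <- character()
  for (s in c("EER", "FARatZeroFRR", "FRRatZeroFAR")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a single rate in [0, 1]", s))
  }
  if (!all(c("threshold", "FAR", "FRR") %in% names(object@roc)))
    msg <- c(msg, "roc must have columns threshold, FAR, FRR")
  if (length(msg)) msg else TRUE
})

#' Closed-set identification (1:N matching) experiment report
#'
#' One rank per probe (rank 1 = the probe's own class template scored
#' strictly highest, ties resolved optimistically), the cumulative match
#' characteristic CMC(r) = fraction of probes identified within rank r,
#' the rank-one rate, and the lowest rank of perfect recognition.
#'
#' @slot ranks integer vector, one rank (>= 1) per probe.
#' @slot cmc numeric vector, recognition rate at ranks 1..C.
#' @slot rankOneRate fraction of probes at rank 1.
#' @slot lowestPerfectRank smallest rank at which CMC reaches 1.
#' @slot templateSeed seed used for the per-class template draw.
#'
#' @seealso [runIdentification()], [identificationRank()]
#' @export
setClass("IdentificationReport",
  representation(
    ranks = "integer",
    cmc = "numeric",
    rankOneRate = "numeric",
    lowestPerfectRank = "integer",
    templateSeed = "integer"
  )
)

setValidity("IdentificationReport", function(object) {
  msg <- character()
  if (length(object@ranks) && any(object@ranks < 1L))
    msg <- c(msg, "ranks must be >= 1")
  if (length(object@cmc)) {
    if (is.unsorted(object@cmc))
      msg <- c(msg, "cmc must be non-decreasing")
    if (abs(object@cmc[length(object@cmc)] - 1) > 1e-12)
      msg <- c(msg, "cmc must reach 1 at the maximum rank")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic vein-image generator
#'
#' Describes a synthetic database emulating a multi-session finger-vein
#' collection: `nClasses` fingers, `nSamples` captures per finger, each
#' class defined by its own dark curvilinear vessel network on a brighter
#' background, each capture perturbed geometrically and photometrically.
#' Identical configuration and master seed always reproduce a bit-identical
#' database.
#'
#' @slot nClasses number of classes (fingers).
#' @slot nSamples captures per class.
#' @slot imageWidth,imageHeight canvas size in pixels (96 x 64 in the
#'   default post-ROI mode, 320 x 240 in full-frame mode).
#' @slot fullFrame logical; render a dark border plus bright finger band so
#'   the ROI detector has work to do.
#' @slot nVesselRange integer range of vessels per class.
#' @slot vesselWidthRange vessel stroke width range, pixels.
#' @slot vesselContrastRange intensity drop range of a vessel below the
#'   background.
#' @slot jitterMax maximum absolute sub-pixel translation per sample, pixels.
#' @slot brightnessRange maximum relative brightness scale deviation per
#'   sample (0.05 = +/-5 percent).
#' @slot blurSigma Gaussian blur standard deviation, pixels.
#' @slot noiseSigma additive Gaussian noise standard deviation, intensity
#'   units.
#' @slot masterSeed integer seed from which all class and sample seeds are
#'   derived.
#'
#' @seealso [syntheticConfig()], [generateDatabase()]
#' @export
setClass("SyntheticConfig",
  representation(
    nClasses = "integer",
    nSamples = "integer",
    imageWidth = "integer",
    imageHeight = "integer",
    fullFrame = "logical",
    nVesselRange = "integer",
    vesselWidthRange = "numeric",
    vesselContrastRange = "numeric",
    jitterMax = "numeric",
    brightnessRange = "numeric",
    blurSigma = "numeric",
    noiseSigma = "numeric",
    masterSeed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nClasses < 1L) msg <- c(msg, "nClasses must be >= 1")
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (object@imageWidth < 3L || object@imageHeight < 3L)
    msg <- c(msg, "image dimensions must be >= 3")
  rng <- function(r) length(r) == 2L && r[1] <= r[2] && all(r > 0)
  if (!rng(object@nVesselRange)) msg <- c(msg, "bad nVesselRange")
  if (!rng(object@vesselWidthRange)) msg <- c(msg, "bad vesselWidthRange")
  if (!rng(object@vesselContrastRange)) msg <- c(msg, "bad vesselContrastRange")
  if (object@jitterMax < 0) msg <- c(msg, "jitterMax must be >= 0")
  if (object@brightnessRange < 0 || object@brightnessRange >= 1)
    msg <- c(msg, "brightnessRange must be in [0, 1)")
  if (object@blurSigma < 0) msg <- c(msg, "blurSigma must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})
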