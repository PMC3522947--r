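#' @rdname CodeMap-class
#' @param object,x a `CodeMap`, `VeinDatabase` or report object.
#' @export
setGeneric("codes", function(object) standardGeneric("codes"))

#' @rdname CodeMap-class
#' @export
setMethod("codes", "CodeMap", function(object) object@codes)

#' @rdname CodeMap-class
#' @export
setGeneric("nOrientations", function(object) standardGeneric("nOrientations"))

#' @rdname CodeMap-class
#' @export
setMethod("nOrientations", "CodeMap", function(object) object@nOrientations)

#' @rdname CodeMap-class
#' @export
setGeneric("variant", function(object) standardGeneric("variant"))

#' @rdname CodeMap-class
#' @export
setMethod("variant", "CodeMap", function(object) object@variant)

#' @rdname CodeMap-class
#' @export
setMethod("dim", "CodeMap", function(x) dim(x@codes))

setMethod("show", "CodeMap", function(object) {
  d <- dim(object@codes)
  cat(sprintf("CodeMap LDC-%s: %d x %d codes, T = %d\n",
              object@variant, d[1], d[2], object@nOrientations))
  tab <- tabulate(as.integer(object@codes) + 1L, object@nOrientations)
  cat("  code histogram:", paste(tab, collapse = " "), "\n")
})

#' @rdname MatchResult-class
#' @param object a `MatchResult`.
#' @export
setGeneric("score", function(object) standardGeneric("score"))

#' @rdname MatchResult-class
#' @export
setMethod("score", "MatchResult", function(object) object@score)

#' @rdname MatchResult-class
#' @export
setGeneric("agreementBitmap", function(object) standardGeneric("agreementBitmap"))

#' @rdname MatchResult-class
#' @export
setMethod("agreementBitmap", "MatchResult", function(object) object@bitmap)

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: score %.4f over %d positions\n",
              object@score, object@codeNum))
})

#' @rdname VeinDatabase-class
#' @param object a `VeinDatabase`.
#' @export
setGeneric("nClasses", function(object) standardGeneric("nClasses"))

#' @rdname VeinDatabase-class
#' @export
setMethod("nClasses", "VeinDatabase", function(object) length(object@classIds))

#' @rdname VeinDatabase-class
#' @export
setGeneric("classIds", function(object) standardGeneric("classIds"))

#' @rdname VeinDatabase-class
#' @export
setMethod("classIds", "VeinDatabase", function(object) object@classIds)

#' @rdname VeinDatabase-class
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' Per-class sample counts, named by class id.
#' @rdname VeinDatabase-class
#' @export
setMethod("nSamples", "VeinDatabase", function(object) {
  stats::setNames(vapply(object@samples, length, 1L), object@classIds)
})

#' Retrieve one sample image.
#'
#' @param db a `VeinDatabase`.
#' @param class class index (integer) or class id (character).
#' @param sample sample index within the class (1-based, protocol order).
#' @return integer grayscale matrix.
#' @export
getSample <- function(db, class, sample) {
  stopifnot(is(db, "VeinDatabase"))
  if (is.character(class)) class <- match(class, db@classIds)
  if (is.na(class) || class < 1L || class > length(db@samples))
    stop("unknown class")
  cls <- db@samples[[class]]
  if (sample < 1L || sample > length(cls)) stop("sample index out of range")
  cls[[sample]]
}

setMethod("show", "VeinDatabase", function(object) {
  ns <- vapply(object@samples, length, 1L)
  d <- if (length(object@samples)) dim(object@samples[[1]][[1]]) else c(0, 0)
  cat(sprintf("VeinDatabase: %d classes, %s samples/class, images %d x %d\n",
              length(object@classIds),
              if (length(unique(ns)) == 1L) ns[1] else
                sprintf("%d-%d", min(ns), max(ns)),
              d[2], d[1]))
})

#' @rdname VerificationReport-class
#' @param object a `VerificationReport`.
#' @export
setGeneric("eer", function(object) standardGeneric("eer"))

#' @rdname VerificationReport-class
#' @export
setMethod("eer", "VerificationReport", function(object) object@EER)

#' @rdname VerificationReport-class
#' @export
setGeneric("genuineScores", function(object) standardGeneric("genuineScores"))

#' @rdname VerificationReport-class
#' @export
setMethod("genuineScores", "VerificationReport",
          function(object) object@genuineScores)

#' @rdname VerificationReport-class
#' @export
setGeneric("imposterScores", function(object) standardGeneric("imposterScores"))

#' @rdname VerificationReport-class
#' @export
setMethod("imposterScores", "VerificationReport",
          function(object) object@imposterScores)

#' @rdname VerificationReport-class
#' @export
setGeneric("rocCurve", function(object) standardGeneric("rocCurve"))

#' @rdname VerificationReport-class
#' @export
setMethod("rocCurve", "VerificationReport", function(object) object@roc)

#' @rdname VerificationReport-class
#' @export
setGeneric("farAtZeroFRR", function(object) standardGeneric("farAtZeroFRR"))

#' @rdname VerificationReport-class
#' @export
setMethod("farAtZeroFRR", "VerificationReport",
          function(object) object@FARatZeroFRR)

#' @rdname VerificationReport-class
#' @export
setGeneric("frrAtZeroFAR", function(object) standardGeneric("frrAtZeroFAR"))

#' @rdname VerificationReport-class
#' @export
setMethod("frrAtZeroFAR", "VerificationReport",
          function(object) object@FRRatZeroFAR)

setMethod("show", "VerificationReport", function(object) {
  cat(sprintf(
    "VerificationReport: %d genuine, %d imposter scores\n  EER %.4f | FAR@zeroFRR %.4f | FRR@zeroFAR %.4f\n",
    length(object@genuineScores), length(object@imposterScores),
    object@EER, object@FARatZeroFRR, object@FRRatZeroFAR))
})

#' @rdname IdentificationReport-class
#' @param object an `IdentificationReport`.
#' @export
setGeneric("ranks", function(object) standardGeneric("ranks"))

#' @rdname IdentificationReport-class
#' @export
setMethod("ranks", "IdentificationReport", function(object) object@ranks)

#' @rdname IdentificationReport-class
#' @export
setGeneric("cmcCurve", function(object) standardGeneric("cmcCurve"))

#' @rdname IdentificationReport-class
#' @export
setMethod("cmcCurve", "IdentificationReport", function(object) object@cmc)

#' @rdname IdentificationReport-class
#' @export
setGeneric("rankOneRate", function(object) standardGeneric("rankOneRate"))

#' @rdname IdentificationReport-class
#' @export
setMethod("rankOneRate", "IdentificationReport",
          function(object) object@rankOneRate)

#' @rdname IdentificationReport-class
#' @export
setGeneric("lowestPerfectRank",
           function(object) standardGeneric("lowestPerfectRank"))

#' @rdname IdentificationReport-class
#' @export
setMethod("lowestPerfectRank", "IdentificationReport",
          function(object) object@lowestPerfectRank)

setMethod("show", "IdentificationReport", function(object) {
  cat(sprintf(
    "IdentificationReport: %d probes, %d ranks\n  rank-one rate %.4f | lowest perfect rank %d\n",
    length(object@ranks), length(object@cmc),
    object@rankOneRate, object@lowestPerfectRank))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d classes x %d samples, %d x %d %s\n  vessels %d-%d, width %.1f-%.1f px, contrast %.0f-%.0f, jitter +/-%.1f px\n  blur sigma %.2f, noise sigma %.2f, brightness +/-%.0f%%, master seed %d\n",
    object@nClasses, object@nSamples, object@imageWidth, object@imageHeight,
    if (object@fullFrame) "(full frame)" else "(post-ROI)",
    object@nVesselRange[1], object@nVesselRange[2],
    object@vesselWidthRange[1], object@vesselWidthRange[2],
    object@vesselContrastRange[1], object@vesselContrastRange[2],
    object@jitterMax, object@blurSigma, object@noiseSigma,
    100 * object@brightnessRange, object@masterSeed))
})
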