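# Verification and identification protocols over a database of code maps:
# genuine/imposter pair construction, threshold-sweep error rates
# (ROC, EER, FAR at zero FRR, FRR at zero FAR), closed-set identification
# ranks with the cumulative match characteristic, and the T sweep.

# Per-class sample counts from a database or a plain integer vector.
.sampleCounts <- function(db) {
  if (is(db, "VeinDatabase")) vapply(db@samples, length, 1L)
  else if (is.numeric(db) && length(db) >= 1L && all(db >= 1)) as.integer(db)
  else stop("db must be a VeinDatabase or a vector of per-class sample counts")
}

#' Build the verification pair lists
#'
#' Genuine pairs are all unordered within-class pairs (full intraclass
#' matching: `C * S(S-1)/2` for C classes of S samples). Imposter pairs are
#' all unordered cross-class pairs among the first `k` samples of every
#' class: `choose(C, 2) * k^2`. Scores are symmetric, so each unordered
#' pair is counted once. For the 136-class, 30-sample collection design
#' with `k = 6` this gives 59,160 genuine and 330,480 imposter pairs.
#'
#' @param db a [VeinDatabase-class], or an integer vector of per-class
#'   sample counts (pair construction needs only the index structure).
#' @param k number of leading samples per class entering interclass
#'   matching (default 6).
#' @return list with integer two-column matrices `genuine` and `imposter`
#'   of global sample indices (class-major order), and `offsets`, the
#'   index of the sample before each class's first.
#' @export
verificationPairs <- function(db, k = 6L) {
  counts <- .sampleCounts(db)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (any(counts < k))
    stop("every class needs at least k samples for interclass matching")
  C <- length(counts)
  off <- c(0L, cumsum(counts))[seq_len(C)]
  # genuine: all within-class unordered pairs
  gen <- do.call(rbind, lapply(seq_len(C), function(ci) {
    s <- counts[ci]
    if (s < 2L) return(matrix(integer(0), 0L, 2L))
    p <- utils::combn(s, 2L)
    cbind(off[ci] + p[1L, ], off[ci] + p[2L, ])
  }))
  # imposter: first-k vs first-k across every unordered class pair
  if (C >= 2L) {
    cp <- utils::combn(C, 2L)
    np <- ncol(cp)
    sA <- rep(rep(seq_len(k), times = k), times = np)
    sB <- rep(rep(seq_len(k), each = k), times = np)
    imp <- cbind(rep(off[cp[1L, ]], each = k * k) + sA,
                 rep(off[cp[2L, ]], each = k * k) + sB)
  } else {
    imp <- matrix(integer(0), 0L, 2L)
  }
  storage.mode(gen) <- "integer"
  storage.mode(imp) <- "integer"
  list(genuine = gen, imposter = imp, offsets = off)
}

#' Threshold-sweep verification metrics
#'
#' Sweeps the decision threshold over the union of all observed scores
#' (plus a sentinel above the maximum). At threshold tau,
#' `FAR(tau)` = fraction of imposter scores >= tau and `FRR(tau)` =
#' fraction of genuine scores < tau, so FAR is non-increasing and FRR
#' non-decreasing in tau. The equal error rate is read off at the FAR/FRR
#' crossing by linear interpolation between the bracketing thresholds.
#' The zero-FRR operating point is the largest threshold rejecting no
#' genuine score (FAR there = fraction of imposters scoring at least the
#' weakest genuine); the zero-FAR point is the smallest threshold
#' accepting no imposter.
#'
#' @param genuine,imposter nonempty numeric score vectors in `[0, 1]`.
#' @return a [VerificationReport-class].
#' @examples
#' r <- rocMetrics(c(0.9, 0.8), c(0.1, 0.2))
#' eer(r)  # 0: supports are disjoint
#' @export
rocMetrics <- function(genuine, imposter) {
  if (!length(genuine) || !length(imposter))
    stop("genuine and imposter score lists must both be nonempty")
  stopifnot(is.numeric(genuine), is.numeric(imposter),
            !anyNA(genuine), !anyNA(imposter))
  g <- sort(genuine); im <- sort(imposter)
  nG <- length(g); nI <- length(im)
  thr <- sort(unique(c(g, im)))
  thr <- c(thr, thr[length(thr)] + 1)       # sentinel: rejects everything
  FAR <- (nI - findInterval(thr, im, left.open = TRUE)) / nI
  FRR <- findInterval(thr, g, left.open = TRUE) / nG
  d <- FAR - FRR                            # non-increasing, starts at +1
  kx <- which(d <= 0)[1]
  EER <- if (is.na(kx)) {
    FAR[length(FAR)]                        # never crosses (cannot happen)
  } else if (d[kx] == 0) {
    FAR[kx]
  } else if (kx == 1L) {
    (FAR[1] + FRR[1]) / 2
  } else {
    a <- d[kx - 1L] / (d[kx - 1L] - d[kx])
    FAR[kx - 1L] + a * (FAR[kx] - FAR[kx - 1L])
  }
  new("VerificationReport",
      genuineScores = as.numeric(genuine),
      imposterScores = as.numeric(imposter),
      roc = data.frame(threshold = thr, FAR = FAR, FRR = FRR),
      EER = EER,
      FARatZeroFRR = mean(imposter >= min(g)),
      FRRatZeroFAR = FRR[which(FAR == 0)[1]])
}

# Extract code maps for every sample of a database and flatten them into
# the columns of one integer matrix (class-major sample order).
extractDatabaseCodes <- function(db, variant = "00", T = 8L,
                                 preprocess = FALSE, ...) {
  stopifnot(is(db, "VeinDatabase"))
  imgs <- unlist(db@samples, recursive = FALSE, use.names = FALSE)
  maps <- lapply(imgs, function(im) {
    if (preprocess) im <- preprocessImage(im, ...)
    extractCodeMap(im, variant, T)@codes
  })
  d <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), d), TRUE)))
    stop("database images yield code maps of differing sizes")
  counts <- vapply(db@samples, length, 1L)
  list(codeMatrix = matrix(unlist(maps, use.names = FALSE),
                           nrow = prod(d), ncol = length(maps)),
       class = rep(seq_along(counts), counts),
       mapDim = d)
}

#' Run the verification experiment on a database
#'
#' Extracts the code map of every sample, scores all genuine and imposter
#' pairs of the verification protocol, and computes the threshold-sweep
#' metrics.
#'
#' @param db a [VeinDatabase-class].
#' @param variant,T descriptor settings, see [extractCodeMap()].
#' @param k leading samples per class used for interclass matching.
#' @param preprocess run [preprocessImage()] on each sample first (for
#'   full-frame databases); post-ROI databases are matched as stored.
#' @param ... passed to [preprocessImage()].
#' @return a [VerificationReport-class].
#' @export
runVerification <- function(db, variant = "00", T = 8L, k = 6L,
                            preprocess = FALSE, ...) {
  ext <- extractDatabaseCodes(db, variant, T, preprocess, ...)
  pairs <- verificationPairs(db, k)
  gen <- scoreColumnPairs(ext$codeMatrix,
                          pairs$genuine[, 1L], pairs$genuine[, 2L])
  imp <- scoreColumnPairs(ext$codeMatrix,
                          pairs$imposter[, 1L], pairs$imposter[, 2L])
  rocMetrics(gen, imp)
}

#' Identification rank of one probe
#'
#' Rank = 1 + number of templates scoring strictly higher than the true
#' class's template. Ties do not increase the rank (optimistic
#' convention); `pessimisticTies = TRUE` counts ties against the probe
#' instead, for sensitivity analysis.
#'
#' @param scores numeric vector of the probe's similarity to every class
#'   template.
#' @param trueIndex position of the probe's own class in `scores`.
#' @param pessimisticTies count tied templates as outranking.
#' @return integer rank >= 1.
#' @export
identificationRank <- function(scores, trueIndex, pessimisticTies = FALSE) {
  stopifnot(trueIndex >= 1L, trueIndex <= length(scores))
  s <- scores[trueIndex]
  extra <- if (pessimisticTies) sum(scores[-trueIndex] == s) else 0L
  as.integer(1L + sum(scores > s) + extra)
}

#' Run the closed-set identification experiment on a database
#'
#' The first `nProbes` samples of each class are the probes; one template
#' per class is drawn (seeded) uniformly from the remaining samples. Every
#' probe is scored against all templates; ranks follow
#' [identificationRank()] and CMC(r) is the fraction of probes with rank
#' at most r.
#'
#' @param db a [VeinDatabase-class]; every class needs more than `nProbes`
#'   samples.
#' @param variant,T descriptor settings.
#' @param nProbes probes per class (default 10).
#' @param templateSeed seed for the per-class template draw (recorded in
#'   the report).
#' @param pessimisticTies see [identificationRank()].
#' @param preprocess,... see [runVerification()].
#' @return an [IdentificationReport-class].
#' @export
runIdentification <- function(db, variant = "00", T = 8L, nProbes = 10L,
                              templateSeed = 1L, pessimisticTies = FALSE,
                              preprocess = FALSE, ...) {
  counts <- .sampleCounts(db)
  nProbes <- as.integer(nProbes)
  if (any(counts <= nProbes))
    stop("every class needs more than nProbes samples (template pool empty)")
  C <- length(counts)
  off <- c(0L, cumsum(counts))[seq_len(C)]
  templateIdx <- withSeed(as.integer(templateSeed), {
    vapply(seq_len(C), function(ci) {
      pool <- (nProbes + 1L):counts[ci]
      off[ci] + pool[sample.int(length(pool), 1L)]
    }, 1L)
  })
  ext <- extractDatabaseCodes(db, variant, T, preprocess, ...)
  probeIdx <- unlist(lapply(seq_len(C), function(ci) off[ci] + seq_len(nProbes)))
  probeClass <- rep(seq_len(C), each = nProbes)
  nP <- length(probeIdx)
  # score every probe against every template
  ia <- rep(probeIdx, each = C)
  ib <- rep(templateIdx, times = nP)
  sc <- matrix(scoreColumnPairs(ext$codeMatrix, ia, ib), nrow = C)
  rk <- vapply(seq_len(nP), function(p) {
    identificationRank(sc[, p], probeClass[p], pessimisticTies)
  }, 1L)
  cmc <- cumsum(tabulate(rk, C)) / nP
  new("IdentificationReport",
      ranks = rk,
      cmc = cmc,
      rankOneRate = cmc[1L],
      lowestPerfectRank = as.integer(which(cmc >= 1 - 1e-12)[1L]),
      templateSeed = as.integer(templateSeed))
}

#' Equal error rate as a function of the number of orientations T
#'
#' Re-runs the full verification pipeline for each requested T and
#' collects the EER, for studying the trade-off between discriminability
#' (large T) and statistical reliability / noise tolerance (small T).
#'
#' @param db a [VeinDatabase-class].
#' @param Tvalues integer vector of orientation counts to evaluate.
#' @param variant,k,preprocess,... see [runVerification()].
#' @return data.frame with columns `T` and `EER`.
#' @export
sweepT <- function(db, Tvalues = c(2L, 4L, 8L, 16L), variant = "00",
                   k = 6L, preprocess = FALSE, ...) {
  stopifnot(length(Tvalues) >= 1L)
  eers <- vapply(Tvalues, function(Tv) {
    eer(runVerification(db, variant, as.integer(Tv), k, preprocess, ...))
  }, numeric(1))
  data.frame(T = as.integer(Tvalues), EER = eers)
}
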