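test_that("verification pair counts match the protocol identities", {
  # full-scale collection design: 136 classes x 30 samples, first-six
  # interclass matching
  p <- verificationPairs(rep(30L, 136L), k = 6L)
  expect_identical(nrow(p$genuine), 59160L)
  expect_identical(nrow(p$imposter), 330480L)
  # small design, cross-checked by exhaustive enumeration
  p2 <- verificationPairs(rep(4L, 3L), k = 2L)
  expect_identical(nrow(p2$genuine), 18L)   # 3 * C(4,2)
  expect_identical(nrow(p2$imposter), 12L)  # C(3,2) * 2^2
  cls <- rep(1:3, each = 4L); smp <- rep(1:4, times = 3L)
  allPairs <- t(utils::combn(12L, 2L))
  genRef <- allPairs[cls[allPairs[, 1]] == cls[allPairs[, 2]], ]
  impRef <- allPairs[cls[allPairs[, 1]] != cls[allPairs[, 2]] &
                     smp[allPairs[, 1]] <= 2 & smp[allPairs[, 2]] <= 2, ]
  sorted <- function(m) m[order(m[, 1], m[, 2]), ]
  expect_equal(sorted(unname(p2$genuine)), sorted(unname(genRef)))
  expect_equal(sorted(unname(p2$imposter)), sorted(unname(impRef)))
  # identity holds across shapes
  for (C in 2:5) for (S in 3:5) for (k in 1:3) {
    p3 <- verificationPairs(rep(S, C), k = k)
    expect_identical(nrow(p3$genuine), as.integer(C * S * (S - 1) / 2))
    expect_identical(nrow(p3$imposter), as.integer(choose(C, 2) * k^2))
  }
  expect_error(verificationPairs(rep(2L, 3L), k = 5L), "at least k")
})

test_that("rocMetrics handles separable, identical and crossing score sets", {
  expect_equal(eer(rocMetrics(c(0.9, 0.8), c(0.1, 0.2))), 0)
  s <- c(0.2, 0.4, 0.4, 0.7)
  expect_equal(eer(rocMetrics(s, s)), 0.5)
  expect_equal(eer(rocMetrics(c(0.6, 0.4), c(0.5, 0.3))), 0.5)
  expect_error(rocMetrics(numeric(0), 0.5), "nonempty")
})

test_that("rocMetrics agrees with exhaustive threshold enumeration", {
  set.seed(17)
  for (rep in 1:40) {
    g <- round(runif(sample(3:40, 1), 0.2, 1), 2)
    i <- round(runif(sample(3:40, 1), 0, 0.8), 2)
    r <- rocMetrics(g, i)
    expect_equal(eer(r), enumRocEER(g, i), tolerance = 1e-12)
    expect_equal(farAtZeroFRR(r), mean(i >= min(g)))
    expect_equal(frrAtZeroFAR(r), mean(g <= max(i)))
  }
})

test_that("ROC sweep is monotone and EER lies in the crossing bracket", {
  set.seed(23)
  g <- rbeta(200, 5, 2); i <- rbeta(300, 2, 5)
  r <- rocMetrics(g, i)
  roc <- rocCurve(r)
  expect_true(all(diff(roc$FAR) <= 0))
  expect_true(all(diff(roc$FRR) >= 0))
  expect_gte(eer(r), 0); expect_lte(eer(r), 1)
  d <- roc$FAR - roc$FRR
  k <- which(d <= 0)[1]
  lo <- min(roc$FAR[k], roc$FRR[k - 1]); hi <- max(roc$FRR[k], roc$FAR[k - 1])
  expect_gte(eer(r), lo - 1e-12)
  expect_lte(eer(r), hi + 1e-12)
})

test_that("identificationRank counts strictly greater scores", {
  expect_identical(identificationRank(c(0.2, 0.9, 0.4), 2), 1L)
  expect_identical(identificationRank(c(0.9, 0.9, 0.9, 0.9, 0.1), 1), 1L)
  expect_identical(identificationRank(c(rep(0.8, 5), 0.5), 6), 6L)
  # pessimistic tie mode counts ties against the probe
  expect_identical(identificationRank(c(0.9, 0.9, 0.9), 2,
                                      pessimisticTies = TRUE), 3L)
})

test_that("runIdentification builds the seeded protocol correctly", {
  db <- generateDatabase(toyConfig(nClasses = 5L, nSamples = 6L,
                                   noiseSigma = 0, jitterMax = 0,
                                   brightnessRange = 0))
  # with no perturbation every sample equals its class template exactly
  r <- runIdentification(db, "00", 8L, nProbes = 3L, templateSeed = 4L)
  expect_identical(length(ranks(r)), 15L)
  expect_equal(rankOneRate(r), 1)
  expect_identical(lowestPerfectRank(r), 1L)
  expect_equal(cmcCurve(r)[nClasses(db)], 1)
  # same seed reproduces, different seed may not pick the same templates
  r2 <- runIdentification(db, "00", 8L, nProbes = 3L, templateSeed = 4L)
  expect_identical(ranks(r), ranks(r2))
  expect_error(runIdentification(db, nProbes = 6L), "more than nProbes")
})

test_that("CMC from hand-assigned scores matches brute force", {
  # 3 classes, 2 probes each, scores fixed by hand
  scores <- list(
    c(0.9, 0.2, 0.1), c(0.3, 0.5, 0.4),   # probes of class 1
    c(0.2, 0.8, 0.1), c(0.6, 0.6, 0.2),   # probes of class 2
    c(0.1, 0.2, 0.9), c(0.5, 0.6, 0.4))   # probes of class 3
  trueCls <- c(1, 1, 2, 2, 3, 3)
  rk <- mapply(identificationRank, scores, trueCls)
  expect_identical(as.integer(rk), c(1L, 3L, 1L, 1L, 1L, 3L))
  cmc <- cumsum(tabulate(rk, 3)) / 6
  expect_equal(cmc, c(4 / 6, 4 / 6, 1))
})

test_that("sweepT reruns the pipeline consistently per T", {
  db <- generateDatabase(toyConfig(nClasses = 6L, nSamples = 4L, seed = 3L))
  sw <- sweepT(db, c(2L, 8L), variant = "00", k = 3L)
  expect_identical(sw$T, c(2L, 8L))
  standalone <- eer(runVerification(db, "00", 8L, k = 3L))
  expect_equal(sw$EER[sw$T == 8L], standalone)
  # two-code maps carry little identity information relative to T = 8
  expect_lte(sw$EER[sw$T == 8L], sw$EER[sw$T == 2L])
})
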