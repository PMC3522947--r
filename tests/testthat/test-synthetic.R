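test_that("class patterns are deterministic and respect configured ranges", {
  cfg <- syntheticConfig(masterSeed = 5L)
  p1 <- generateClassPattern(cfg, 3L)
  p2 <- generateClassPattern(cfg, 3L)
  expect_identical(p1, p2)
  nv <- vapply(1:30, function(ci) length(generateClassPattern(cfg, ci)), 1L)
  expect_true(all(nv >= 3L & nv <= 7L))
  for (v in generateClassPattern(cfg, 9L)) {
    expect_gte(v$width, 2); expect_lte(v$width, 6)
    expect_gte(v$contrast, 60); expect_lte(v$contrast, 120)
  }
  # distinct seeds give distinct curve sets
  pats <- lapply(1:100, function(ci) generateClassPattern(cfg, ci))
  keys <- vapply(pats, function(p) paste(round(p[[1]]$ctrlY, 6), collapse = ","),
                 "")
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("unperturbed samples are pixel-identical and vessels dark", {
  cfg <- syntheticConfig(nClasses = 2L, nSamples = 3L, jitterMax = 0,
                         noiseSigma = 0, brightnessRange = 0, masterSeed = 2L)
  pat <- generateClassPattern(cfg, 1L)
  s1 <- renderSample(pat, cfg, 1L, 1L)
  s2 <- renderSample(pat, cfg, 1L, 2L)
  expect_identical(s1, s2)
  # without blur, centerline pixels sit at least min contrast - 1 below
  # the background
  cfg0 <- syntheticConfig(nClasses = 1L, nSamples = 1L, jitterMax = 0,
                          noiseSigma = 0, brightnessRange = 0, blurSigma = 0,
                          masterSeed = 2L)
  img <- renderSample(generateClassPattern(cfg0, 1L), cfg0, 1L, 1L)
  for (v in generateClassPattern(cfg0, 1L)) {
    fy <- splinefun(v$ctrlX, v$ctrlY, method = "natural")
    j <- 48L
    i <- round(1 + fy((j - 1) / 95) * 63)
    expect_lte(img[i, j], 180 - (min(v$contrast, 170) - 1))
  }
  expect_true(all(img <= 180L))
})

test_that("the database is deterministic, on-disk layout round-trips", {
  cfg <- syntheticConfig(nClasses = 3L, nSamples = 4L, masterSeed = 13L)
  d1 <- file.path(tempdir(), "synthdb1")
  d2 <- file.path(tempdir(), "synthdb2")
  unlink(c(d1, d2), recursive = TRUE)
  db <- generateDatabase(cfg, d1)
  generateDatabase(cfg, d2)
  expect_identical(nClasses(db), 3L)
  expect_identical(unname(nSamples(db)), rep(4L, 3L))
  files <- list.files(d1, recursive = TRUE)
  expect_identical(sum(grepl("\\.pgm$", files)), 12L)
  expect_true("manifest.json" %in% files)
  expect_identical(length(list.dirs(d1, recursive = FALSE)), 3L)
  # byte-identical trees from identical config
  for (f in grep("pgm$", files, value = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e5),
                     readBin(file.path(d2, f), "raw", 1e5))
  }
  # reading back reproduces the in-memory images
  rd <- readDatabase(d1)
  expect_identical(classIds(rd), classIds(db))
  expect_identical(getSample(rd, 2, 3), unname(getSample(db, 2, 3)))
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_identical(manifest$config$masterSeed, 13L)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("within-class samples resemble each other more than cross-class", {
  db <- generateDatabase(syntheticConfig(nClasses = 10L, nSamples = 3L,
                                         masterSeed = 6L))
  mad <- function(a, b) mean(abs(a - b))
  within <- unlist(lapply(1:10, function(ci) {
    c(mad(getSample(db, ci, 1), getSample(db, ci, 2)),
      mad(getSample(db, ci, 1), getSample(db, ci, 3)))
  }))
  cross <- unlist(lapply(1:9, function(ci)
    mad(getSample(db, ci, 1), getSample(db, ci + 1, 1))))
  expect_lt(mean(within), mean(cross))
})

test_that("the separability gap closes under extreme perturbations", {
  gap <- function(cfg) {
    db <- generateDatabase(cfg)
    r <- runVerification(db, "00", 8L, k = 3L)
    mean(genuineScores(r)) - mean(imposterScores(r))
  }
  gDefault <- gap(toyConfig(nClasses = 8L, nSamples = 3L, seed = 10L))
  gExtreme <- gap(toyConfig(nClasses = 8L, nSamples = 3L, seed = 10L,
                            jitterMax = 12, noiseSigma = 60))
  expect_gt(gDefault, 0)
  expect_lt(gExtreme, gDefault / 2)
})

test_that("imposter scores concentrate near chance agreement 1/T", {
  db <- generateDatabase(syntheticConfig(nClasses = 12L, nSamples = 1L,
                                         masterSeed = 8L))
  r <- verificationPairs(rep(1L, 12L), k = 1L)
  ext <- veinLDC:::extractDatabaseCodes(db, "00", 8L)
  imp <- veinLDC:::scoreColumnPairs(ext$codeMatrix,
                                    r$imposter[, 1], r$imposter[, 2])
  # independent patterns share structure only through the flat background;
  # agreement stays within a loose band around 1/8
  expect_gt(mean(imp), 0.125 / 2)
  expect_lt(mean(imp), 0.125 * 2)
})

test_that("full-frame mode renders a dark border around the finger band", {
  cfg <- syntheticConfig(nClasses = 1L, nSamples = 1L, fullFrame = TRUE,
                         masterSeed = 3L)
  img <- getSample(generateDatabase(cfg), 1, 1)
  expect_identical(dim(img), c(240L, 320L))
  border <- mean(img[1:10, ])
  band <- mean(img[110:130, 100:220])
  expect_lt(border, 60)
  expect_gt(band, 2 * border)
})
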