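test_that("directionalComponents follows the neighbor convention", {
  img <- matrix(50, 3, 3)
  expect_equal(directionalComponents(img, 2, 2, "00"),
               c(vv = 0, vh = 0))
  # right neighbor 10, left 0, top = bottom
  img2 <- matrix(50, 3, 3); img2[2, 3] <- 10; img2[2, 1] <- 0
  expect_equal(directionalComponents(img2, 2, 2, "00"), c(vv = 10, vh = 0))
  # diagonals: top-right 9, bottom-left 4, bottom-right 7, top-left 7
  img3 <- matrix(50, 3, 3)
  img3[1, 3] <- 9; img3[3, 1] <- 4; img3[3, 3] <- 7; img3[1, 1] <- 7
  expect_equal(directionalComponents(img3, 2, 2, "45"), c(vv = 5, vh = 0))
  expect_error(directionalComponents(img, 1, 2, "00"), "interior")
})

test_that("orientationAngle maps components onto [0, 2*pi]", {
  expect_equal(orientationAngle(1, 0), pi)
  expect_equal(orientationAngle(0, 0), pi)  # zero-pair convention
  expect_equal(orientationAngle(-1, -1), pi / 4)
  expect_equal(orientationAngle(0, 1), 3 * pi / 2)
  expect_equal(orientationAngle(-1, 0), 2 * pi)
  # sign-case table equivalence on all quadrants
  for (vv in c(-9, -1, 1, 9)) for (vh in c(-7, -2, 2, 7)) {
    th <- atan(vh / vv)
    expected <- if (vh > 0 && vv > 0) th + pi
      else if (vh > 0 && vv < 0) th + 2 * pi
      else if (vh < 0 && vv < 0) th
      else th + pi
    expect_equal(orientationAngle(vv, vh), expected)
  }
})

test_that("quantizeOrientation rounds to the nearest of T sectors", {
  expect_identical(quantizeOrientation(0, 8), 0L)
  expect_identical(quantizeOrientation(2 * pi, 8), 0L)      # wrap-around
  expect_identical(quantizeOrientation(pi, 8), 4L)
  expect_identical(quantizeOrientation(pi / 4, 8), 1L)
  # sector centers t * 2*pi/T map to t for several T
  for (T in c(2L, 4L, 6L, 8L, 10L, 12L, 16L)) {
    centers <- (0:(T - 1)) * 2 * pi / T
    expect_identical(quantizeOrientation(centers, T), 0:(T - 1))
  }
  # boundary behavior: just below a sector edge stays, just above advances
  expect_identical(quantizeOrientation(pi / 8 - 1e-9, 8), 0L)
  expect_identical(quantizeOrientation(pi / 8 + 1e-9, 8), 1L)
  expect_error(quantizeOrientation(-0.1, 8), "0, 2")
})

test_that("extractCodeMap obeys the dimension contract and conventions", {
  cm <- extractCodeMap(matrix(10, 10, 10), "00", 8)
  expect_identical(dim(cm), c(8L, 8L))
  expect_true(all(codes(cm) == 4L))          # zero-pair pixels code T/2
  expect_identical(dim(extractCodeMap(makeRandomImage(1, 5, 5))), c(3L, 3L))
  expect_error(extractCodeMap(matrix(1, 2, 5)), "3 x 3")
  # vertical step: all codes in the boundary columns agree, and match the
  # per-pixel oracle
  step <- cbind(matrix(0, 8, 4), matrix(200, 8, 4))
  sc <- codes(extractCodeMap(step, "00", 8))
  ref <- naiveCodeMap(step, "00", 8)
  expect_identical(sc, ref)
  for (j in seq_len(ncol(sc))) expect_length(unique(sc[, j]), 1L)
})

test_that("extractCodeMap equals the naive per-pixel oracle", {
  set.seed(42)
  for (rep in 1:25) {
    h <- sample(3:32, 1); w <- sample(3:32, 1)
    img <- matrix(sample(0:255, h * w, TRUE), h, w)
    for (variant in c("00", "45")) for (T in c(2L, 4L, 8L, 16L)) {
      expect_identical(codes(extractCodeMap(img, variant, T)),
                       naiveCodeMap(img, variant, T))
    }
  }
})

test_that("codes always lie in [0, T) and extraction is deterministic", {
  img <- makeRandomImage(7, 20, 25)
  for (T in c(2L, 4L, 6L, 8L, 10L, 12L, 16L)) {
    cm <- codes(extractCodeMap(img, "00", T))
    expect_true(all(cm >= 0L & cm < T))
  }
  expect_identical(extractCodeMap(img, "45", 8), extractCodeMap(img, "45", 8))
})

test_that("90-degree rotation shifts codes by T/4 on zero-pair-free images", {
  for (seed in 1:10) {
    img <- makeSmoothImage(seed)
    for (T in c(4L, 8L, 16L)) {
      rotated <- codes(extractCodeMap(rotCCW(img), "00", T))
      shifted <- (rotCCW(codes(extractCodeMap(img, "00", T))) + T %/% 4L) %% T
      expect_identical(rotated, shifted)
    }
  }
})

test_that("the diagonal variant equals the substitution oracle", {
  img <- makeRandomImage(12, 16, 16)
  got <- codes(extractCodeMap(img, "45", 8))
  h <- nrow(img); w <- ncol(img)
  ref <- matrix(NA_integer_, h - 2, w - 2)
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    vv <- img[i - 1, j + 1] - img[i + 1, j - 1]   # x7 - x3
    vh <- img[i + 1, j + 1] - img[i - 1, j - 1]   # x5 - x1
    ref[i - 1, j - 1] <- quantizeOrientation(orientationAngle(vv, vh), 8)
  }
  expect_identical(got, ref)
})
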