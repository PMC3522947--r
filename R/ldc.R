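# Local Directional Code extraction. Every interior pixel of a grayscale
# image is coded by its local gradient orientation, quantized into T
# dominant directions. Two neighbor conventions: LDC-00 uses the
# axis-aligned differences (right - left, top - bottom); LDC-45 the
# diagonal ones. Border pixels are ignored, so the code map of a W x H
# image is (W - 2) x (H - 2).
#
# 3x3 neighborhood labels around the center (row index grows downward):
#   x1 x8 x7        x1 = top-left,    x8 = top,    x7 = top-right
#   x2 xc x6        x2 = left,                     x6 = right
#   x3 x4 x5        x3 = bottom-left, x4 = bottom, x5 = bottom-right
# LDC-00: v_v = x6 - x2, v_h = x8 - x4
# LDC-45: v_v = x7 - x3, v_h = x5 - x1

#' Directional difference components at one pixel
#'
#' The two outputs of the vertical and horizontal difference filters in a
#' 3x3 neighborhood. For variant `"00"`: `v_v = X(i, j+1) - X(i, j-1)` and
#' `v_h = X(i-1, j) - X(i+1, j)` (row index increases downward, so `v_h`
#' is top minus bottom). For variant `"45"` the filters are rotated onto
#' the diagonals: `v_v = X(i-1, j+1) - X(i+1, j-1)`,
#' `v_h = X(i+1, j+1) - X(i-1, j-1)`.
#'
#' @param img grayscale numeric matrix.
#' @param i,j interior pixel position (`2 <= i <= H-1`, `2 <= j <= W-1`).
#' @param variant `"00"` (axis-aligned) or `"45"` (diagonal).
#' @return named numeric vector `c(vv =, vh =)`.
#' @export
directionalComponents <- function(img, i, j, variant = c("00", "45")) {
  variant <- match.arg(variant)
  checkGrayImage(img, minDim = 3L)
  if (i < 2L || i > nrow(img) - 1L || j < 2L || j > ncol(img) - 1L)
    stop("(i, j) must be an interior pixel")
  if (variant == "00") {
    c(vv = img[i, j + 1] - img[i, j - 1],
      vh = img[i - 1, j] - img[i + 1, j])
  } else {
    c(vv = img[i - 1, j + 1] - img[i + 1, j - 1],
      vh = img[i + 1, j + 1] - img[i - 1, j - 1])
  }
}

#' Gradient orientation angle on the full circle
#'
#' Maps the two directional components onto the full circle:
#' `theta' = atan2(v_h, v_v) + pi`, with `atan2(0, 0)` defined as 0 so a
#' zero-gradient pixel gets `theta' = pi` (and hence code `T/2`). This
#' reproduces the per-sign-quadrant case table of the classic mapping
#' while avoiding the division in `arctan(v_h / v_v)` when `v_v = 0`.
#'
#' @param vv,vh directional components (vertical- and horizontal-filter
#'   outputs).
#' @return angle in radians, in `[0, 2*pi]`.
#' @export
orientationAngle <- function(vv, vh) {
  # R's atan2(0, 0) is already 0, matching the zero-pair convention
  atan2(vh, vv) + pi
}

#' Quantize an orientation angle into T dominant directions
#'
#' Nearest-sector rounding: `t = floor(theta' / (2*pi/T) + 1/2) mod T`.
#' Sector centers sit at `t * 2*pi/T` (for T = 8 the eight half-axis and
#' diagonal directions `t * pi/4`), each sector extending half a width to
#' either side; `theta' = 2*pi` wraps back to code 0.
#'
#' @param theta angle(s) in `[0, 2*pi]`.
#' @param T number of dominant orientations (>= 2).
#' @return integer code(s) in `[0, T)`.
#' @export
quantizeOrientation <- function(theta, T = 8L) {
  stopifnot(T >= 2L)
  if (any(theta < 0 | theta > 2 * pi + 1e-12))
    stop("theta must lie in [0, 2*pi]")
  as.integer(floor(theta / (2 * pi / T) + 0.5) %% T)
}

#' Extract the Local Directional Code map of an image
#'
#' One pass over all interior pixels: directional components, orientation
#' angle, quantization. Border pixels are ignored, so the result has
#' dimensions `(H - 2) x (W - 2)` for an `H x W` input.
#'
#' @param img grayscale numeric matrix, at least 3 x 3, values 0-255.
#' @param variant `"00"` (axis-aligned neighbors) or `"45"` (diagonal).
#' @param T number of dominant orientations (default 8).
#' @return a [CodeMap-class].
#' @examples
#' img <- matrix(rep(c(0, 0, 200, 200), each = 6), nrow = 6)
#' extractCodeMap(img, "00", T = 8)
#' @export
extractCodeMap <- function(img, variant = c("00", "45"), T = 8L) {
  variant <- match.arg(variant)
  checkGrayImage(img, minDim = 3L)
  T <- as.integer(T)
  stopifnot(T >= 2L)
  h <- nrow(img); w <- ncol(img)
  ic <- 2:(h - 1); jc <- 2:(w - 1)
  if (variant == "00") {
    vv <- img[ic, jc + 1, drop = FALSE] - img[ic, jc - 1, drop = FALSE]
    vh <- img[ic - 1, jc, drop = FALSE] - img[ic + 1, jc, drop = FALSE]
  } else {
    vv <- img[ic - 1, jc + 1, drop = FALSE] - img[ic + 1, jc - 1, drop = FALSE]
    vh <- img[ic + 1, jc + 1, drop = FALSE] - img[ic - 1, jc - 1, drop = FALSE]
  }
  theta <- atan2(vh, vv) + pi
  codes <- matrix(as.integer(floor(theta / (2 * pi / T) + 0.5) %% T),
                  nrow = h - 2L, ncol = w - 2L)
  new("CodeMap", codes = codes, nOrientations = T, variant = variant)
}

#' Construct a CodeMap from raw codes
#'
#' For deserialization and testing; validity checks enforce the code range.
#'
#' @param codes integer matrix with values in `[0, T)`.
#' @param variant `"00"` or `"45"`.
#' @param T number of dominant orientations.
#' @return a [CodeMap-class].
#' @export
codeMap <- function(codes, variant = c("00", "45"), T = 8L) {
  variant <- match.arg(variant)
  storage.mode(codes) <- "integer"
  new("CodeMap", codes = codes, nOrientations = as.integer(T),
      variant = variant)
}
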