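# Preprocessing chain: gray conversion -> ROI detection -> bilinear size
# normalization -> min-max gray normalization. Each stage is independently
# callable; preprocessImage() runs them in order.

#' Convert an RGB image to 8-bit grayscale
#'
#' Standard luminance combination `Y = 0.299 R + 0.587 G + 0.114 B`,
#' rounded half-up to the nearest integer and clamped to `[0, 255]`.
#'
#' @param img integer array `H x W x 3` with channel values 0-255.
#' @return integer matrix `H x W`.
#' @examples
#' px <- array(c(255, 0, 0), c(1, 1, 3))
#' rgbToGray(px)  # 76
#' @export
rgbToGray <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("img must be an H x W x 3 array")
  if (anyNA(img) || any(img < 0) || any(img > 255))
    stop("channel values must be in [0, 255]")
  y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  out <- matrix(clamp255(roundHalfUp(y)), dim(img)[1], dim(img)[2])
  storage.mode(out) <- "integer"
  out
}

# 3x3 Sobel vertical-edge response (detects vertical edges / horizontal
# intensity change), correlation with [-1 0 1; -2 0 2; -1 0 1]. Response is
# defined on interior pixels; returned matrix has the source dimensions with
# a zero border so indices line up.
sobelVertical <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  ic <- 2:(h - 1); jc <- 2:(w - 1)
  out[ic, jc] <-
    (img[ic - 1, jc + 1] + 2 * img[ic, jc + 1] + img[ic + 1, jc + 1]) -
    (img[ic - 1, jc - 1] + 2 * img[ic, jc - 1] + img[ic + 1, jc - 1])
  out
}

#' Detect the finger region of interest
#'
#' Applies the 3x3 Sobel vertical-edge mask; the columns spanned by
#' responses whose magnitude exceeds `edgeThreshold` times the maximum
#' response give the horizontal extent, and the transposed mask gives the
#' vertical extent the same way. The returned box is the intersection
#' rectangle.
#'
#' @param img grayscale integer matrix, at least 3 x 3.
#' @param edgeThreshold fraction of the maximum Sobel magnitude a response
#'   must exceed to count as an edge (default 0.25).
#' @return list with `minRow`, `maxRow`, `minCol`, `maxCol` (1-based,
#'   inclusive).
#' @seealso [cropROI()]
#' @export
detectROI <- function(img, edgeThreshold = 0.25) {
  checkGrayImage(img, minDim = 3L)
  stopifnot(edgeThreshold > 0, edgeThreshold <= 1)
  gv <- abs(sobelVertical(img))        # vertical edges -> column extent
  gh <- abs(t(sobelVertical(t(img))))  # transposed mask -> row extent
  if (max(gv) == 0 && max(gh) == 0)
    stop("no edge found: image has no gradient (unusable capture)")
  colHit <- which(apply(gv >= edgeThreshold * max(gv), 2, any) & max(gv) > 0)
  rowHit <- which(apply(gh >= edgeThreshold * max(gh), 1, any) & max(gh) > 0)
  if (!length(colHit) || !length(rowHit))
    stop("no edge found in one direction: cannot bound the finger region")
  box <- list(minRow = min(rowHit), maxRow = max(rowHit),
              minCol = min(colHit), maxCol = max(colHit))
  if (box$minRow >= box$maxRow || box$minCol >= box$maxCol)
    stop("degenerate region of interest")
  box
}

#' @rdname detectROI
#' @param box an ROI box as returned by `detectROI`.
#' @export
cropROI <- function(img, box) {
  stopifnot(all(c("minRow", "maxRow", "minCol", "maxCol") %in% names(box)))
  if (box$minRow < 1L || box$maxRow > nrow(img) ||
      box$minCol < 1L || box$maxCol > ncol(img))
    stop("box lies outside the image")
  img[box$minRow:box$maxRow, box$minCol:box$maxCol, drop = FALSE]
}

#' Resize a grayscale image by bilinear interpolation
#'
#' Align-corners convention: source corner pixels map exactly onto
#' destination corner pixels. Interpolated values are rounded half-up, so
#' output stays within the global min/max of the source (no overshoot).
#'
#' @param img grayscale numeric matrix, at least 2 x 2.
#' @param outWidth,outHeight destination size in pixels (defaults 96 x 64,
#'   the normalized ROI size used for feature extraction).
#' @return integer matrix `outHeight x outWidth`.
#' @export
resizeBilinear <- function(img, outWidth = 96L, outHeight = 64L) {
  checkGrayImage(img)
  if (nrow(img) < 2L || ncol(img) < 2L)
    stop("source must be at least 2 x 2 for bilinear interpolation")
  stopifnot(outWidth >= 1L, outHeight >= 1L)
  srcPos <- function(n, outN) {
    if (outN == 1L) rep(1, 1L)
    else 1 + (seq_len(outN) - 1) * (n - 1) / (outN - 1)
  }
  ri <- srcPos(nrow(img), outHeight)
  ci <- srcPos(ncol(img), outWidth)
  r0 <- pmin(floor(ri), nrow(img) - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), ncol(img) - 1L); fc <- ci - c0
  # bilinear blend of the four bracketing pixels, vectorized over the grid
  tl <- img[r0, c0, drop = FALSE];     tr <- img[r0, c0 + 1, drop = FALSE]
  bl <- img[r0 + 1, c0, drop = FALSE]; br <- img[r0 + 1, c0 + 1, drop = FALSE]
  wr <- matrix(fr, outHeight, outWidth)
  wc <- matrix(fc, outHeight, outWidth, byrow = TRUE)
  val <- (1 - wr) * (1 - wc) * tl + (1 - wr) * wc * tr +
         wr * (1 - wc) * bl + wr * wc * br
  out <- roundHalfUp(val)
  storage.mode(out) <- "integer"
  out
}

#' Min-max gray normalization
#'
#' Linearly stretches intensities so the minimum maps to 0 and the maximum
#' to 255: `round(255 * (X - Xmin) / (Xmax - Xmin))`, rounded half-up. A
#' constant image has no stretch and is rejected as a degenerate capture.
#'
#' @param img grayscale numeric matrix with at least two distinct values.
#' @return integer matrix, min 0 and max 255.
#' @export
grayNormalize <- function(img) {
  checkGrayImage(img)
  lo <- min(img); hi <- max(img)
  if (hi == lo)
    stop("constant image: gray normalization undefined (degenerate capture)")
  out <- roundHalfUp(255 * (img - lo) / (hi - lo))
  storage.mode(out) <- "integer"
  out
}

#' Full preprocessing chain
#'
#' Runs the four normalization stages in order: RGB-to-gray (skipped for
#' grayscale input), Sobel ROI detection and crop, bilinear resize to the
#' normalized feature size, min-max gray normalization.
#'
#' @param img grayscale matrix or `H x W x 3` RGB array.
#' @param edgeThreshold see [detectROI()].
#' @param outWidth,outHeight normalized ROI size (defaults 96 x 64).
#' @return integer matrix `outHeight x outWidth`, gray-normalized.
#' @export
preprocessImage <- function(img, edgeThreshold = 0.25,
                            outWidth = 96L, outHeight = 64L) {
  if (length(dim(img)) == 3L) img <- rgbToGray(img)
  box <- detectROI(img, edgeThreshold)
  roi <- cropROI(img, box)
  grayNormalize(resizeBilinear(roi, outWidth, outHeight))
}
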