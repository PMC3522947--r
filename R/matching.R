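# Exact-agreement matching of two code maps. No translation or rotation
# search: maps are compared position-wise, robustness to placement comes
# from the preprocessing normalization.

#' Match two code maps by exact per-position agreement
#'
#' The agreement bitmap marks every position where the two maps carry the
#' same code; the similarity score is the fraction of agreeing positions
#' (number of 1s in the bitmap over the total number of compared codes),
#' so it lies in `[0, 1]` and is symmetric in its arguments. Maps are only
#' comparable when dimensions, variant and T all agree.
#'
#' @param codeA,codeB [CodeMap-class] objects of identical dimensions,
#'   variant and number of orientations.
#' @return a [MatchResult-class].
#' @examples
#' a <- codeMap(matrix(0:3, 2, 2), "00", 8)
#' b <- codeMap(matrix(c(0L, 1L, 5L, 6L), 2, 2), "00", 8)
#' score(matchScore(a, b))  # 0.5
#' @export
matchScore <- function(codeA, codeB) {
  stopifnot(is(codeA, "CodeMap"), is(codeB, "CodeMap"))
  if (!identical(dim(codeA@codes), dim(codeB@codes)))
    stop("incomparable code maps: dimensions differ")
  if (codeA@nOrientations != codeB@nOrientations)
    stop("incomparable code maps: T differs")
  if (codeA@variant != codeB@variant)
    stop("incomparable code maps: variant differs")
  bitmap <- codeA@codes == codeB@codes
  n <- length(bitmap)
  new("MatchResult", bitmap = bitmap, score = sum(bitmap) / n,
      codeNum = as.integer(n))
}

# Batch scorer used by the evaluation protocols: code maps flattened into
# the columns of an integer matrix; scores for index pairs (ia, ib) are
# computed in chunks to bound memory.
scoreColumnPairs <- function(codeMatrix, ia, ib, chunk = 4096L) {
  stopifnot(length(ia) == length(ib))
  n <- length(ia)
  out <- numeric(n)
  npos <- nrow(codeMatrix)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out[s:e] <- colSums(codeMatrix[, ia[s:e], drop = FALSE] ==
                        codeMatrix[, ib[s:e], drop = FALSE]) / npos
  }
  out
}
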