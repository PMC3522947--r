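# Raster I/O. PNG goes through the png package; PGM/PPM (netpbm) and
# uncompressed BMP are parsed here directly.

# -- netpbm ------------------------------------------------------------------

# Tokenizer over the header of a netpbm file held as a raw vector.
# Returns tokens and the offset of the first byte after the last token.
pnmHeaderTokens <- function(raw, n) {
  toks <- character(0)
  i <- 1L
  len <- length(raw)
  while (length(toks) < n && i <= len) {
    b <- raw[i]
    if (b == charToRaw("#")) {            # comment to end of line
      while (i <= len && !raw[i] %in% charToRaw("\n")) i <- i + 1L
      i <- i + 1L
    } else if (b %in% charToRaw(" \t\r\n")) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= len && !raw[j] %in% charToRaw(" \t\r\n#")) j <- j + 1L
      toks <- c(toks, rawToChar(raw[i:(j - 1L)]))
      i <- j
    }
  }
  if (length(toks) < n) stop("truncated netpbm header")
  # exactly one whitespace byte separates header from raster data
  list(tokens = toks, dataOffset = i + 1L)
}

pnmComments <- function(raw, end = length(raw)) {
  txt <- rawToChar(raw[seq_len(min(length(raw), end))])
  m <- gregexpr("#[^\n]*", txt)[[1]]
  if (m[1] == -1L) return(character(0))
  sub("^#\\s*", "", regmatches(txt, list(m))[[1]])
}

#' Read a PGM or PPM image
#'
#' Supports binary `P5`/`P6` and ASCII `P2`/`P3` with maxval up to 255.
#' Color (PPM) input is returned as an `H x W x 3` integer array; grayscale
#' (PGM) as an `H x W` integer matrix.
#'
#' @param path file path.
#' @return integer matrix (PGM) or 3-way array (PPM), values 0-255.
#' @export
readPNM <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported netpbm magic: ", magic)
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  hdr <- pnmHeaderTokens(raw, 4L)
  w <- as.integer(hdr$tokens[2]); h <- as.integer(hdr$tokens[3])
  maxval <- as.integer(hdr$tokens[4])
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) stop("bad netpbm dimensions")
  if (is.na(maxval) || maxval < 1L || maxval > 255L)
    stop("only maxval <= 255 supported")
  nvals <- w * h * nch
  if (magic %in% c("P5", "P6")) {
    vals <- as.integer(raw[hdr$dataOffset + seq_len(nvals) - 1L])
  } else {
    txt <- rawToChar(raw[hdr$dataOffset:length(raw)])
    txt <- gsub("#[^\n]*", "", txt)
    vals <- as.integer(strsplit(trimws(txt), "\\s+")[[1]])[seq_len(nvals)]
  }
  if (anyNA(vals)) stop("truncated netpbm raster")
  att <- pnmComments(raw, hdr$dataOffset - 1L)
  out <- if (nch == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0L, c(h, w, 3L))
    for (c in 1:3) a[, , c] <- matrix(vals[seq(c, nvals, by = 3L)],
                                      nrow = h, ncol = w, byrow = TRUE)
    a
  }
  attr(out, "comments") <- att
  attr(out, "maxval") <- maxval
  out
}

#' Write a grayscale matrix as binary PGM (P5)
#'
#' @param img integer matrix with values in `[0, maxval]`.
#' @param path destination file.
#' @param maxval maximum code/intensity value recorded in the header.
#' @param comment optional header comment line(s).
#' @export
writePGM <- function(img, path, maxval = 255L, comment = NULL) {
  stopifnot(is.matrix(img))
  if (any(img < 0) || any(img > maxval))
    stop("pixel values exceed maxval")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0("P5\n",
                paste0(vapply(comment, function(x) paste0("# ", x, "\n"),
                              ""), collapse = ""),
                ncol(img), " ", nrow(img), "\n", maxval, "\n")
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  writeBin(as.raw(as.integer(t(img))), con)
  invisible(path)
}

# -- BMP ---------------------------------------------------------------------

#' Read an uncompressed BMP image
#'
#' Supports the common BI_RGB encodings: 24-bit true color and 8-bit
#' paletted, bottom-up or top-down row order. Returns an `H x W x 3`
#' integer RGB array (palette entries are expanded).
#'
#' @param path file path.
#' @return integer array `H x W x 3`, values 0-255.
#' @export
readBMP <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (rawToChar(raw[1:2]) != "BM") stop("not a BMP file")
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  dataOff <- u32(10L)
  hdrSize <- u32(14L)
  if (hdrSize < 40L) stop("unsupported BMP header")
  w <- u32(18L)
  hRaw <- u32(22L)
  topDown <- hRaw > 2^31
  h <- if (topDown) as.integer(2^32 - hRaw) else as.integer(hRaw)
  bpp <- u16(28L)
  if (u32(30L) != 0L) stop("compressed BMP not supported")
  if (!bpp %in% c(8L, 24L)) stop("only 8- and 24-bit BMP supported")
  out <- array(0L, c(h, w, 3L))
  stride <- ((w * bpp / 8 + 3) %/% 4) * 4
  rowIdx <- if (topDown) seq_len(h) else rev(seq_len(h))
  if (bpp == 24L) {
    for (r in seq_len(h)) {
      off <- dataOff + (r - 1L) * stride
      px <- as.integer(raw[off + seq_len(3L * w)])
      i <- rowIdx[r]
      out[i, , 1] <- px[seq(3, 3 * w, 3)]   # stored BGR
      out[i, , 2] <- px[seq(2, 3 * w, 3)]
      out[i, , 3] <- px[seq(1, 3 * w, 3)]
    }
  } else {
    nPal <- u32(46L)
    if (nPal == 0L) nPal <- 256L
    palOff <- 14L + hdrSize
    pal <- matrix(as.integer(raw[palOff + seq_len(4L * nPal)]),
                  ncol = 4L, byrow = TRUE)    # B G R reserved
    for (r in seq_len(h)) {
      off <- dataOff + (r - 1L) * stride
      idx <- as.integer(raw[off + seq_len(w)]) + 1L
      i <- rowIdx[r]
      out[i, , 1] <- pal[idx, 3]
      out[i, , 2] <- pal[idx, 2]
      out[i, , 3] <- pal[idx, 1]
    }
  }
  out
}

# -- unified grayscale reader ------------------------------------------------

#' Read an image file as an 8-bit grayscale matrix
#'
#' Dispatches on file extension: PNG (via the png package), PGM/PPM
#' (netpbm), or uncompressed BMP. Color input is converted with the
#' luminance weights of [rgbToGray()]; grayscale input is returned as-is.
#'
#' @param path file path (`.png`, `.pgm`, `.ppm`, `.bmp`).
#' @return integer matrix, intensities 0-255, rows = image rows.
#' @export
readImageGray <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      x <- png::readPNG(path)
      if (length(dim(x)) == 2L) roundHalfUp(x * 255)
      else {
        a <- roundHalfUp(x[, , 1:3, drop = FALSE] * 255)
        rgbToGray(a)
      }
    },
    pgm = , ppm = {
      x <- readPNM(path)
      if (length(dim(x)) == 3L) rgbToGray(x) else x
    },
    bmp = rgbToGray(readBMP(path)),
    stop("unsupported image format: .", ext)
  )
  storage.mode(img) <- "integer"
  attr(img, "comments") <- NULL
  attr(img, "maxval") <- NULL
  img
}

# -- code map serialization --------------------------------------------------

#' Serialize and deserialize code maps
#'
#' Code maps round-trip losslessly through two plain formats: binary PGM
#' (`P5`) with codes stored raw and header maxval `T - 1`, and CSV. In both,
#' a header comment records the variant and T so the deserialized map is
#' fully comparable.
#'
#' @param cm a [CodeMap-class].
#' @param path destination/source file; format chosen by extension
#'   (`.pgm` or `.csv`).
#' @return `writeCodeMap` returns `path` invisibly; `readCodeMap` a
#'   `CodeMap`.
#' @export
writeCodeMap <- function(cm, path) {
  stopifnot(is(cm, "CodeMap"))
  meta <- sprintf("LDC variant=%s T=%d", cm@variant, cm@nOrientations)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    if (cm@nOrientations > 256L) stop("PGM stores codes up to 255 only")
    writePGM(cm@codes, path, maxval = max(1L, cm@nOrientations - 1L),
             comment = meta)
  } else if (ext == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", meta), con)
    utils::write.table(cm@codes, con, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else stop("unsupported code map format: .", ext)
  invisible(path)
}

#' @rdname writeCodeMap
#' @export
readCodeMap <- function(path) {
  ext <- tolower(tools::file_ext(path))
  parseMeta <- function(comments) {
    m <- grep("LDC variant=", comments, value = TRUE)
    if (!length(m)) stop("file carries no LDC metadata header")
    list(variant = sub(".*variant=(\\S+).*", "\\1", m[1]),
         T = as.integer(sub(".*T=(\\d+).*", "\\1", m[1])))
  }
  if (ext == "pgm") {
    img <- readPNM(path)
    meta <- parseMeta(attr(img, "comments"))
    codes <- unclass(img)
    attr(codes, "comments") <- NULL
    attr(codes, "maxval") <- NULL
  } else if (ext == "csv") {
    lines <- readLines(path)
    meta <- parseMeta(grep("^#", lines, value = TRUE))
    body <- grep("^#", lines, value = TRUE, invert = TRUE)
    codes <- as.matrix(utils::read.table(text = body, sep = ",",
                                         colClasses = "integer"))
    dimnames(codes) <- NULL
  } else stop("unsupported code map format: .", ext)
  storage.mode(codes) <- "integer"
  new("CodeMap", codes = codes, nOrientations = meta$T, variant = meta$variant)
}

#' Write a code map as a viewable PNG
#'
#' Display helper only: codes are stretched to `[0, 255]` by
#' `255 / (T - 1)`, which is lossy for recognition purposes — use
#' [writeCodeMap()] for storage.
#'
#' @param cm a [CodeMap-class].
#' @param path destination `.png`.
#' @export
writeCodeMapPNG <- function(cm, path) {
  stopifnot(is(cm, "CodeMap"))
  vis <- roundHalfUp(cm@codes * (255 / max(1L, cm@nOrientations - 1L)))
  png::writePNG(vis / 255, path)
  invisible(path)
}
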