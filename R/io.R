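#' Read a grayscale image
#'
#' Reads PGM (P2 ascii or P5 binary), PNG or TIFF files into a numeric matrix
#' with intensities in `[0, 255]`. Inputs with more than 8 bits per sample are
#' rescaled by max-value division (a 16-bit sample `v` becomes
#' `v / 65535 * 255`), so the full dynamic range maps onto `[0, 255]`.
#' Multi-channel inputs are converted to luminance with the ITU-R BT.601
#' weights `0.299 R + 0.587 G + 0.114 B` (an alpha channel, if present, is
#' dropped).
#'
#' @param path path to a `.pgm`, `.png`, `.tif` or `.tiff` file.
#' @return numeric matrix (rows = image rows, top to bottom) in `[0, 255]`.
#' @seealso [write_image()], [make_phantom()]
#' @examples
#' f <- tempfile(fileext = ".pgm")
#' write_image(matrix(100, 32, 32), f)
#' img <- read_image(f)
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("path must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop("cannot read image: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    pgm = read_pgm(path),
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path) * 255,
    stop("unsupported image format: '.", ext,
         "' (supported: pgm, png, tif, tiff)", call. = FALSE)
  )
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L) {
      px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    } else {
      px <- px[, , 1]  # gray+alpha: keep the gray channel
    }
  }
  px <- pmin(pmax(px, 0), 255)
  assert_gray(px, what = paste0("image read from '", path, "'"))
  px
}

#' Write a grayscale image
#'
#' Writes an 8-bit single-channel PGM or PNG file. Intensities are quantized
#' with round-half-up (`127.6` is stored as `128`) and clipped to `[0, 255]`;
#' a write-then-read round trip therefore reproduces the image up to the
#' 0.5-intensity quantization bound.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param path output path ending in `.pgm` or `.png`.
#' @param ascii for PGM output, write the text `P2` variant (default) rather
#'   than binary `P5`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, ascii = TRUE) {
  assert_gray(image)
  q <- quantize8(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = write_pgm(q, path, ascii = ascii),
    png = png::writePNG(q / 255, target = path),
    stop("unsupported output format: '.", ext, "' (supported: pgm, png)",
         call. = FALSE)
  )
  invisible(path)
}

# -- PGM (portable graymap), P2 ascii and P5 binary ---------------------------
# No installed package reads PGM, and the format is a 10-line parser; values
# are returned already rescaled to [0, 255] by max-value division.

read_pgm <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  n <- length(raw)
  ws <- as.raw(c(9L, 10L, 13L, 32L))
  pos <- 1L
  next_token <- function() {
    repeat {
      while (pos <= n && raw[pos] %in% ws) pos <<- pos + 1L
      if (pos <= n && raw[pos] == as.raw(35L)) {  # '#' comment to end of line
        while (pos <= n && raw[pos] != as.raw(10L)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= n && !(raw[pos] %in% ws)) pos <<- pos + 1L
    if (start >= pos) stop("malformed PGM header in ", path, call. = FALSE)
    rawToChar(raw[start:(pos - 1L)])
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (magic '", magic, "'): ", path, call. = FALSE)
  width <- as.integer(next_token())
  height <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(width) || is.na(height) || is.na(maxval) || maxval < 1L)
    stop("malformed PGM header in ", path, call. = FALSE)
  npix <- width * height
  if (magic == "P2") {
    vals <- scan(text = rawToChar(raw[pos:n]), what = double(),
                 n = npix, quiet = TRUE)
  } else {
    pos <- pos + 1L  # exactly one whitespace byte after maxval
    if (maxval < 256L) {
      if (pos + npix - 1L > n) stop("truncated PGM data in ", path, call. = FALSE)
      vals <- as.integer(raw[pos:(pos + npix - 1L)])
    } else {
      if (pos + 2L * npix - 1L > n) stop("truncated PGM data in ", path, call. = FALSE)
      vals <- readBin(raw[pos:(pos + 2L * npix - 1L)], "integer", n = npix,
                      size = 2L, signed = FALSE, endian = "big")
    }
  }
  if (length(vals) < npix) stop("truncated PGM data in ", path, call. = FALSE)
  m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  m / maxval * 255
}

write_pgm <- function(q, path, ascii = TRUE) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- sprintf("%s\n%d %d\n255\n", if (ascii) "P2" else "P5",
                    ncol(q), nrow(q))
  writeBin(charToRaw(header), con)
  if (ascii) {
    rows <- apply(q, 1L, paste, collapse = " ")
    writeBin(charToRaw(paste0(paste(rows, collapse = "\n"), "\n")), con)
  } else {
    writeBin(as.raw(as.integer(t(q))), con)
  }
  invisible(path)
}
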