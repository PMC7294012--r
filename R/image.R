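#' Grayscale image conventions
#'
#' Images are plain numeric matrices with intensities in `[0, 255]`, stored at
#' full precision internally (restoration filters produce weighted averages;
#' quantization to 8 bits happens only on file write). Rows index the vertical
#' axis top-to-bottom, columns the horizontal axis, matching how
#' [png::readPNG()] lays images out. The minimum supported size is 16 x 16,
#' which leaves room for 5 x 5 statistic windows plus the border policy.
#'
#' @param x object to validate / coerce.
#' @return `as_gray_image()` returns a validated numeric matrix.
#' @examples
#' img <- as_gray_image(matrix(100, 16, 16))
#' @export
as_gray_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("a grayscale image must be a numeric matrix", call. = FALSE)
  storage.mode(x) <- "double"
  assert_gray(x)
  x
}

# shared validator; `what` names the argument in error messages
assert_gray <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 16L || ncol(x) < 16L)
    stop(what, " must be at least 16 x 16 pixels, got ",
         nrow(x), " x ", ncol(x), call. = FALSE)
  if (anyNA(x))
    stop(what, " contains missing values", call. = FALSE)
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 255)
    stop(what, " intensities must lie in [0, 255], observed range [",
         signif(rng[1], 6), ", ", signif(rng[2], 6), "]", call. = FALSE)
  invisible(x)
}

assert_mask <- function(mask, image, what = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(what, " must be a logical matrix", call. = FALSE)
  if (anyNA(mask))
    stop(what, " contains missing values", call. = FALSE)
  if (!identical(dim(mask), dim(image)))
    stop(what, " dimensions (", nrow(mask), " x ", ncol(mask),
         ") do not match the image (", nrow(image), " x ", ncol(image), ")",
         call. = FALSE)
  invisible(mask)
}

assert_odd_window <- function(w, what = "window") {
  if (length(w) != 1L || !is.numeric(w) || w < 3 || w %% 2 != 1)
    stop(what, " must be a single odd integer >= 3", call. = FALSE)
  invisible(as.integer(w))
}

# quantize to 8 bits with round-half-up, the rule used at every file write
quantize8 <- function(x) {
  pmin(pmax(floor(x + 0.5), 0), 255)
}
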