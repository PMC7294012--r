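#' Standard median filter
#'
#' Replaces every pixel by the median of its window (reflect borders),
#' whether or not the pixel is corrupted — the classic baseline whose
#' indiscriminate smoothing motivates switching filters: it removes isolated
#' impulses but also erases thin clean detail such as one-pixel-wide lines
#' or microcalcification-like specks.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param window odd window side, 3 by default.
#' @return filtered numeric matrix.
#' @export
standard_median <- function(image, window = 3L) {
  assert_gray(image)
  window <- assert_odd_window(window)
  cpp_sliding_median(image, window)
}

#' Adaptive median filter
#'
#' The classic two-level adaptive median: starting from a 3 x 3 window, the
#' window grows by 2 while its median is an extreme (equal to the window
#' minimum or maximum, hence itself suspect), up to `max_window`; the pixel
#' is then replaced by the final window's median only if the pixel itself is
#' an extreme of that window, and passed through unchanged otherwise. This
#' targets salt-and-pepper impulses while leaving non-extreme pixels
#' untouched.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param max_window odd maximum window side, 11 by default.
#' @return filtered numeric matrix.
#' @export
adaptive_median <- function(image, max_window = 11L) {
  assert_gray(image)
  max_window <- assert_odd_window(max_window, "max_window")
  cpp_adaptive_median(image, max_window)
}
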