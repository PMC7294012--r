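#' Mean squared error between two images
#'
#' @param original,restored numeric matrices of one shape.
#' @return mean over all pixels of the squared intensity difference; 0 iff
#'   the images are identical.
#' @export
mse <- function(original, restored) {
  if (!is.matrix(original) || !is.matrix(restored) ||
      !identical(dim(original), dim(restored)))
    stop("original and restored must be matrices of one shape",
         call. = FALSE)
  mean((as.numeric(original) - as.numeric(restored))^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(255^2 / mse)` in decibels, with the peak fixed at 255 (the
#' 8-bit convention; not the per-image maximum). A perfect restoration
#' (`mse = 0`) returns `Inf`, the documented sentinel.
#'
#' @inheritParams mse
#' @return PSNR in dB, or `Inf` for identical images.
#' @examples
#' a <- matrix(0, 16, 16); b <- a + 1
#' psnr(a, b)  # 10 * log10(65025) ~= 48.13 dB
#' @export
psnr <- function(original, restored) {
  m <- mse(original, restored)
  if (m == 0) Inf else 10 * log10(255^2 / m)
}

# recall / false-positive rate of a detected mask against ground truth
detection_scores <- function(detected, truth) {
  tp <- sum(detected & truth)
  fp <- sum(detected & !truth)
  pos <- sum(truth)
  neg <- length(truth) - pos
  c(recall = if (pos == 0L) NA_real_ else tp / pos,
    fpr = if (neg == 0L) NA_real_ else fp / neg)
}
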