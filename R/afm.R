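#' Configuration for the adaptive fuzzy median restorer
#'
#' The adaptive fuzzy median filter replaces a flagged pixel by a fuzzy
#' weighted aggregate of the non-corrupted intensities in a window around it.
#' The window starts at `initial_window` and grows by 2 whenever the clean
#' sample is too small (`< min_clean` values) or its median sits at an
#' extreme of the window — the classic adaptive-median trigger that a median
#' equal to the window minimum or maximum is itself likely an impulse. The
#' fuzzy weights come from a triangular membership centred on the clean
#' median with half-width `fuzzy_spread`, floored at `weight_floor` so the
#' aggregate is always defined: large `fuzzy_spread` approaches the clean
#' mean, small `fuzzy_spread` approaches the clean median.
#'
#' @param initial_window,max_window odd window sides, `3 <= initial <= max`.
#' @param fuzzy_spread intensity half-width of the triangular membership.
#' @param min_clean minimum number of clean window values required before the
#'   window stops growing.
#' @param weight_floor small positive lower bound on any membership weight.
#' @return an object of class `afm_config`.
#' @export
afm_config <- function(initial_window = 3L, max_window = 11L,
                       fuzzy_spread = 20, min_clean = 3L,
                       weight_floor = 1e-3) {
  initial_window <- assert_odd_window(initial_window, "initial_window")
  max_window <- assert_odd_window(max_window, "max_window")
  if (initial_window > max_window)
    stop("initial_window must not exceed max_window", call. = FALSE)
  if (fuzzy_spread <= 0) stop("fuzzy_spread must be positive", call. = FALSE)
  if (min_clean < 1L) stop("min_clean must be at least 1", call. = FALSE)
  if (weight_floor <= 0) stop("weight_floor must be positive", call. = FALSE)
  structure(list(initial_window = initial_window, max_window = max_window,
                 fuzzy_spread = fuzzy_spread,
                 min_clean = as.integer(min_clean),
                 weight_floor = weight_floor),
            class = "afm_config")
}

#' Restore a single flagged pixel with the adaptive fuzzy median
#'
#' Grows the window per the `afm_config` rules, then returns the fuzzy
#' weighted aggregate of the clean (unflagged) window intensities; if the
#' largest window holds no clean value at all, falls back to the plain median
#' of all window values. The result is a convex combination of the clean
#' values used, so it is bounded by their extremes.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param mask logical matrix, `TRUE` = corrupted.
#' @param row,col 1-based indices of a *flagged* pixel; passing a clean pixel
#'   is an error — restoration must not touch clean pixels.
#' @param cfg an [afm_config()].
#' @return restored intensity (scalar).
#' @export
afm_restore_pixel <- function(image, mask, row, col, cfg = afm_config()) {
  assert_gray(image)
  assert_mask(mask, image)
  if (row < 1L || row > nrow(image) || col < 1L || col > ncol(image))
    stop("pixel (", row, ", ", col, ") is outside the image", call. = FALSE)
  if (!mask[row, col])
    stop("pixel (", row, ", ", col, ") is not flagged as corrupted; ",
         "restoration must not touch clean pixels", call. = FALSE)
  cpp_afm_pixel(image, mask, row - 1L, col - 1L, cfg$initial_window,
                cfg$max_window, cfg$fuzzy_spread, cfg$min_clean,
                cfg$weight_floor)
}

#' Adaptive fuzzy median restoration of all flagged pixels
#'
#' Replaces every flagged pixel by [afm_restore_pixel()] and leaves every
#' unflagged pixel bit-identical. All restorations read the *input* image:
#' there is no cascading within one pass (cascading across detector
#' iterations is the detector's job).
#'
#' @inheritParams afm_restore_pixel
#' @return restored numeric matrix.
#' @examples
#' img <- matrix(50, 16, 16); img[8, 8] <- 255
#' mask <- matrix(FALSE, 16, 16); mask[8, 8] <- TRUE
#' afm_restore(img, mask)[8, 8]  # 50
#' @export
afm_restore <- function(image, mask, cfg = afm_config()) {
  assert_gray(image)
  assert_mask(mask, image)
  cpp_afm_restore(image, mask, cfg$initial_window, cfg$max_window,
                  cfg$fuzzy_spread, cfg$min_clean, cfg$weight_floor)
}
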