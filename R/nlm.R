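#' Configuration for mask-restricted non-local means
#'
#' The restoration filter is a non-local means extended in three ways for
#' switching (impulse) denoising: it is applied only to detected noisy
#' pixels, patch distances ignore corrupted positions, and both distances and
#' the averaged intensities come from a *reference* image — in the full
#' pipeline, the working image the detection cascade has already restored
#' with the adaptive fuzzy median.
#'
#' @param patch_radius patch half-side in pixels (3 gives 7 x 7 patches);
#'   radius 0 compares bare pixels.
#' @param search_radius search-window half-side (10 gives 21 x 21 windows);
#'   must be at least `patch_radius`. Setting it to the image size makes the
#'   search global.
#' @param bandwidth_h intensity scale of the weight decay
#'   `exp(-d / bandwidth_h^2)`; larger values flatten the weights towards an
#'   unweighted average of the clean candidates.
#' @param min_clean_fraction fraction of patch positions that must be clean
#'   in *both* patches for the pair to be comparable; incomparable candidates
#'   get weight 0.
#' @return an object of class `nlm_config`.
#' @export
nlm_config <- function(patch_radius = 3L, search_radius = 10L,
                       bandwidth_h = 10, min_clean_fraction = 0.5) {
  patch_radius <- as.integer(patch_radius)
  search_radius <- as.integer(search_radius)
  if (patch_radius < 0L) stop("patch_radius must be >= 0", call. = FALSE)
  if (search_radius < max(patch_radius, 1L))
    stop("search_radius must be at least patch_radius (and >= 1)",
         call. = FALSE)
  if (bandwidth_h <= 0) stop("bandwidth_h must be positive", call. = FALSE)
  if (min_clean_fraction < 0 || min_clean_fraction > 1)
    stop("min_clean_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(patch_radius = patch_radius, search_radius = search_radius,
                 bandwidth_h = bandwidth_h,
                 min_clean_fraction = min_clean_fraction),
            class = "nlm_config")
}

#' Mask-aware patch distance
#'
#' Mean squared intensity difference between the patches centred at `p` and
#' `q` in the reference image, computed only over patch positions where both
#' patches are clean (unflagged), with reflect padding at borders. If the
#' clean overlap covers less than `min_clean_fraction` of the patch the pair
#' is incomparable and `NA` is returned.
#'
#' @param reference numeric matrix in `[0, 255]`.
#' @param mask logical matrix, `TRUE` = corrupted.
#' @param p,q length-2 integer vectors `c(row, col)`, 1-based.
#' @param cfg an [nlm_config()].
#' @return non-negative scalar, or `NA` when the patches are incomparable.
#' @export
patch_distance <- function(reference, mask, p, q, cfg = nlm_config()) {
  assert_gray(reference, "reference")
  assert_mask(mask, reference)
  if (length(p) != 2L || length(q) != 2L)
    stop("p and q must be length-2 (row, col) vectors", call. = FALSE)
  cpp_patch_distance(reference, mask, p[1] - 1L, p[2] - 1L,
                     q[1] - 1L, q[2] - 1L, cfg$patch_radius,
                     cfg$min_clean_fraction)
}

#' Non-local means restoration of flagged pixels
#'
#' For each flagged pixel, candidate pixels are the clean (unflagged) pixels
#' in the search window; each comparable candidate `q` gets weight
#' `exp(-patch_distance(p, q) / bandwidth_h^2)` and contributes the
#' *reference* intensity at `q`. The restored value is the weight-normalized
#' average — a convex combination of contributing reference intensities. If
#' every candidate is incomparable (or there are none), the pixel falls back
#' to the adaptive fuzzy median of the reference. Unflagged pixels pass
#' through bit-identical.
#'
#' @param image numeric matrix in `[0, 255]` whose flagged pixels are to be
#'   restored.
#' @param mask logical matrix, `TRUE` = corrupted.
#' @param reference numeric matrix the patch comparisons and averaged
#'   intensities are taken from.
#' @param cfg an [nlm_config()].
#' @param afm_cfg an [afm_config()] for the fallback.
#' @return restored numeric matrix.
#' @export
nlm_restore <- function(image, mask, reference, cfg = nlm_config(),
                        afm_cfg = afm_config()) {
  assert_gray(image)
  assert_gray(reference, "reference")
  assert_mask(mask, image)
  if (!identical(dim(reference), dim(image)))
    stop("reference dimensions do not match the image", call. = FALSE)
  cpp_nlm_restore(image, mask, reference, cfg$patch_radius,
                  cfg$search_radius, cfg$bandwidth_h,
                  cfg$min_clean_fraction, afm_cfg$initial_window,
                  afm_cfg$max_window, afm_cfg$fuzzy_spread,
                  afm_cfg$min_clean, afm_cfg$weight_floor)
}

#' Denoise an image: detect impulses, then restore them
#'
#' The full switching pipeline: the coarse/fine detection cascade flags
#' impulse pixels (restoring them with the adaptive fuzzy median as it goes),
#' and the non-local means filter then re-restores exactly those pixels of
#' the *original* image, using the cascade's restored working image as its
#' reference (an external reference may be supplied instead). Never-flagged
#' pixels are returned bit-identical to the input. The pipeline is a pure
#' function of its arguments: no hidden randomness.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param det_cfg a [detection_config()].
#' @param nlm_cfg an [nlm_config()].
#' @param reference optional external reference image; by default the
#'   detector's restored working image is used.
#' @param return_details if `TRUE`, return a list with the restored `image`
#'   and the `detection` object instead of just the matrix.
#' @return restored numeric matrix (or a list, see `return_details`).
#' @examples
#' clean <- make_phantom(phantom_spec(height = 64, width = 64))
#' noisy <- corrupt(clean, noise_spec("random_valued", p = 0.1, seed = 2))
#' out <- denoise(noisy$image)
#' psnr(clean, out) > psnr(clean, noisy$image)
#' @export
denoise <- function(image, det_cfg = detection_config(),
                    nlm_cfg = nlm_config(), reference = NULL,
                    return_details = FALSE) {
  assert_gray(image)
  det <- detect_impulses(image, det_cfg)
  ref <- if (is.null(reference)) det$restored else {
    assert_gray(reference, "reference")
    reference
  }
  out <- nlm_restore(image, det$mask, ref, nlm_cfg, det_cfg$afm_config)
  if (return_details) list(image = out, detection = det) else out
}
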