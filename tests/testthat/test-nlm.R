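test_that("patch distances behave as mean squared clean-overlap differences", {
  img <- matrix(100, 16, 16)
  none <- matrix(FALSE, 16, 16)
  cfg <- nlm_config()
  expect_equal(patch_distance(img, none, c(8, 8), c(8, 8), cfg), 0)  # self
  expect_equal(patch_distance(img, none, c(5, 5), c(11, 11), cfg), 0)

  # bare-pixel (radius 0) variant: squared difference of the two intensities
  img[4, 4] <- 10
  img[12, 12] <- 16
  cfg0 <- nlm_config(patch_radius = 0, search_radius = 10)
  expect_equal(patch_distance(img, none, c(4, 4), c(12, 12), cfg0), 36)

  # corrupted positions are excluded; too little clean overlap -> NA
  mask <- none
  mask[4, 4] <- TRUE
  expect_true(is.na(patch_distance(img, mask, c(4, 4), c(12, 12), cfg0)))
  img[12, 13] <- 16  # off-centre, so the masked centre pair doesn't hide it
  cfg_loose <- nlm_config(patch_radius = 1, search_radius = 10,
                          min_clean_fraction = 0.5)
  d <- patch_distance(img, mask, c(4, 4), c(12, 12), cfg_loose)
  expect_equal(d, ((100 - 16)^2) / 8)  # 8 clean pairs, one differing
})

test_that("an empty mask makes nlm_restore an identity", {
  img <- random_image(32, 32, seed = 41)
  none <- matrix(FALSE, 32, 32)
  expect_identical(nlm_restore(img, none, img), img)
})

test_that("a constant reference restores flagged pixels to the constant", {
  img <- matrix(70, 32, 32)
  img[10, 10] <- 255
  mask <- matrix(FALSE, 32, 32)
  mask[10, 10] <- TRUE
  ref <- matrix(70, 32, 32)
  out <- nlm_restore(img, mask, ref)
  expect_equal(out[10, 10], 70)
  expect_identical(out[!mask], img[!mask])
})

test_that("patch similarity keeps restoration inside the local intensity region", {
  # two-region image: left half 40, right half 160
  ref <- cbind(matrix(40, 32, 16), matrix(160, 32, 16))
  img <- ref
  img[16, 8] <- 255
  mask <- matrix(FALSE, 32, 32)
  mask[16, 8] <- TRUE
  out <- nlm_restore(img, mask, ref)
  expect_gte(out[16, 8], 40)
  expect_lt(out[16, 8], 40 + 1e-3)  # right-region patches get ~zero weight
})

test_that("restored values are convex combinations of clean reference candidates", {
  ref <- make_phantom(small_phantom(32, seed = 51))
  img <- ref
  mask <- withr::with_seed(52, matrix(runif(32 * 32) < 0.15, 32, 32))
  img[mask] <- withr::with_seed(53, sample(0:255, sum(mask), replace = TRUE))
  cfg <- nlm_config()
  out <- nlm_restore(img, mask, ref, cfg)
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    rows <- max(1, r - cfg$search_radius):min(32, r + cfg$search_radius)
    cols <- max(1, c - cfg$search_radius):min(32, c + cfg$search_radius)
    cand <- ref[rows, cols][!mask[rows, cols]]
    expect_gte(out[r, c], min(cand) - 1e-9)
    expect_lte(out[r, c], max(cand) + 1e-9)
  }
})

test_that("infinite bandwidth tends to the unweighted mean of comparable clean candidates", {
  ref <- make_phantom(small_phantom(32, seed = 54))
  img <- ref
  mask <- withr::with_seed(55, matrix(runif(32 * 32) < 0.1, 32, 32))
  img[mask] <- 255
  cfg <- nlm_config(bandwidth_h = 1e7)
  out <- nlm_restore(img, mask, ref, cfg)
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    rows <- max(1, r - cfg$search_radius):min(32, r + cfg$search_radius)
    cols <- max(1, c - cfg$search_radius):min(32, c + cfg$search_radius)
    cand <- c()
    for (qr in rows) for (qc in cols) {
      if (mask[qr, qc]) next
      if (!is.na(patch_distance(ref, mask, c(r, c), c(qr, qc), cfg)))
        cand <- c(cand, ref[qr, qc])
    }
    expect_equal(out[r, c], mean(cand), tolerance = 1e-6)
  }
})

test_that("pixels with no comparable candidate fall back to the adaptive fuzzy median", {
  ref <- random_image(16, 16, seed = 61)
  img <- ref
  mask <- matrix(FALSE, 16, 16)
  mask[7:9, 7:9] <- TRUE  # the whole search neighbourhood of (8, 8) is flagged
  cfg <- nlm_config(patch_radius = 1, search_radius = 1)
  out <- nlm_restore(img, mask, ref, cfg)
  expect_equal(out[8, 8], afm_restore_pixel(ref, mask, 8, 8))
})

test_that("denoising improves PSNR over the noisy input and the pipeline is deterministic", {
  clean <- make_phantom(phantom_spec(height = 64, width = 64, seed = 62))
  noisy <- corrupt(clean, noise_spec("random_valued", p = 0.1, seed = 2))$image
  out1 <- denoise(noisy)
  out2 <- denoise(noisy)
  expect_identical(out1, out2)
  expect_gt(psnr(clean, out1), psnr(clean, noisy))

  noisy30 <- corrupt(clean, noise_spec("random_valued", p = 0.3, seed = 2))$image
  expect_gt(psnr(clean, denoise(noisy30)),
            psnr(clean, standard_median(noisy30)))
})

test_that("nlm configuration is validated", {
  expect_error(nlm_config(patch_radius = -1), "patch_radius")
  expect_error(nlm_config(patch_radius = 5, search_radius = 3),
               "at least patch_radius")
  expect_error(nlm_config(bandwidth_h = 0), "positive")
  expect_error(nlm_config(min_clean_fraction = 1.2), "\\[0, 1\\]")
})
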