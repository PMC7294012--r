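test_that("the per-cluster decision flags by |pixel - AMED| against the cluster threshold", {
  img <- matrix(50, 16, 16)
  amed <- matrix(50, 16, 16)
  cmap <- matrix(4L, 16, 16)
  thr <- c(45, 30, 20, 15)
  expect_false(any(decide_cluster(img, amed, cmap, thr)))  # constant image

  img[2, 2] <- 255; cmap[2, 2] <- 1L   # |205| > 45 -> flagged
  img[3, 3] <- 60                      # |10| <= 15 in cluster 4 -> clean
  flags <- decide_cluster(img, amed, cmap, thr)
  expect_true(flags[2, 2])
  expect_false(flags[3, 3])
  expect_equal(sum(flags), 1L)
  expect_error(decide_cluster(img, amed[1:8, 1:8], cmap, thr), "shape")
})

test_that("a noise-free constant image passes through with an empty mask", {
  img <- matrix(90, 32, 32)
  det <- detect_impulses(img)
  expect_false(any(det$mask))
  expect_identical(det$restored, img)
  out <- denoise(img)
  expect_identical(out, img)
})

test_that("isolated impulses on a constant background are caught in the first coarse pass", {
  img <- matrix(50, 32, 32)
  pts <- cbind(c(5, 12, 20, 27, 16), c(7, 25, 4, 30, 16))
  img[pts] <- 255
  det <- detect_impulses(img)
  expect_true(all(det$mask[pts]))
  expect_equal(sum(det$mask), 5L)
  trace <- tidy(det)
  expect_equal(trace$new_flags[1], 5L)
  expect_true(all(trace$new_flags[-1] == 0L))
})

test_that("masks accumulate: coarse iterations nest and the final mask contains the coarse mask", {
  clean <- make_phantom(phantom_spec(height = 64, width = 64, seed = 21))
  noisy <- corrupt(clean, noise_spec("fixed_valued", p = 0.2, seed = 3))$image
  m1 <- detect_coarse(noisy, detection_config(coarse_iterations = 1))$mask
  m4 <- detect_coarse(noisy, detection_config(coarse_iterations = 4))$mask
  expect_true(all(m4[m1]))  # union never shrinks with more iterations

  det <- detect_impulses(noisy)
  expect_true(all(det$mask[det$coarse_mask]))
  fine <- detect_fine(det$restored, det$mask)
  expect_true(all(fine$mask[det$mask]))  # output mask always contains prior
})

test_that("raising every threshold never enlarges the detected mask", {
  clean <- make_phantom(phantom_spec(height = 64, width = 64, seed = 22))
  noisy <- corrupt(clean, noise_spec("random_valued", p = 0.15, seed = 5))$image
  lo <- detect_impulses(noisy, detection_config())$mask
  hi <- detect_impulses(noisy, detection_config(
    coarse_thresholds = c(45, 30, 20, 15) + 10,
    fine_thresholds = c(25, 18, 12, 8) + 10))$mask
  expect_true(all(lo[hi]))  # hi-threshold mask is a subset
})

test_that("a low-contrast residual missed by the coarse stage is caught by the fine stage", {
  # smooth diagonal ramp: in a 5 x 5 window the deviations from the window
  # median put a +18 perturbation in cluster 3 (1 < mROR <= 2), between the
  # coarse threshold 20 and the fine threshold 12
  a <- 5
  base <- outer(seq_len(16), seq_len(16), function(r, c) a * (r + c)) + 10
  img <- base
  img[8, 8] <- base[8, 8] + 18
  coarse <- detect_coarse(img)
  expect_false(coarse$mask[8, 8])
  det <- detect_impulses(img)
  expect_true(det$mask[8, 8])
})

test_that("the cascade beats a single-pass single-threshold detector at matched false-positive rate", {
  clean <- make_phantom(phantom_spec(height = 128, width = 128, seed = 30))
  res <- corrupt(clean, noise_spec("fixed_valued", p = 0.4, seed = 11))
  det <- detect_impulses(res$image)
  truth <- res$mask
  cascade_recall <- sum(det$mask & truth) / sum(truth)
  cascade_fpr <- sum(det$mask & !truth) / sum(!truth)

  # one global threshold on |pixel - AMED| of the noisy image, chosen as the
  # smallest threshold whose FPR does not exceed the cascade's
  dev <- abs(res$image - amed_map(res$image))
  single_recall <- 0
  for (t in 0:255) {
    flags <- dev > t
    if (sum(flags & !truth) / sum(!truth) <= cascade_fpr) {
      single_recall <- sum(flags & truth) / sum(truth)
      break
    }
  }
  expect_gt(cascade_recall, single_recall)
})

test_that("never-flagged pixels survive the full pipeline bit-identically", {
  clean <- make_phantom(phantom_spec(height = 64, width = 64, seed = 23))
  noisy <- corrupt(clean, noise_spec("fixed_valued", p = 0.3, seed = 7))$image
  res <- denoise(noisy, return_details = TRUE)
  expect_identical(res$image[!res$detection$mask], noisy[!res$detection$mask])
})

test_that("detection objects summarise and validate cleanly", {
  img <- matrix(50, 32, 32); img[10, 10] <- 255
  det <- detect_impulses(img)
  g <- glance(det)
  expect_equal(g$n_flagged, 1L)
  expect_equal(g$fraction_flagged, 1 / 1024)
  expect_output(print(det), "1 pixels flagged")
  expect_error(detection_config(fine_thresholds = c(50, 30, 20, 15)),
               "strictly below")
  expect_error(detection_config(coarse_iterations = 0), "at least 1")
  expect_error(detection_config(coarse_thresholds = c(45, 30)), "4 values")
})
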