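test_that("window_values returns the window sample under both border policies", {
  img <- random_image(16, 16, seed = 1)
  cfg <- robust_config()
  expect_length(window_values(img, 8, 8, cfg), 25)
  expect_length(window_values(img, 1, 1, cfg), 25)  # reflect pads to full size
  cfg_ex <- robust_config(border = "exclude_partial")
  expect_length(window_values(img, 1, 1, cfg_ex), 9)   # 3 x 3 clipped corner
  expect_length(window_values(img, 1, 8, cfg_ex), 15)  # 3 x 5 clipped edge
  expect_error(window_values(img, 0, 5, cfg), "outside")
})

test_that("AMED, AMAD and NAMAD match hand-computed window statistics", {
  img <- matrix(100, 16, 16)
  cfg <- robust_config()
  expect_true(all(amed_map(img, cfg) == 100))
  expect_true(all(namad_map(img, cfg) == 0))

  # a 5 x 5 block holding 0..24 centred at (8, 8): median 12, AMAD 6
  img2 <- matrix(12, 16, 16)
  img2[6:10, 6:10] <- matrix(0:24, 5, 5)
  expect_equal(amed_map(img2, cfg)[8, 8], 12)
  expect_equal(namad_map(img2, cfg)[8, 8], 6 / 0.6457)

  # single impulse in a constant image: AMED ignores it, NAMAD stays 0
  img3 <- matrix(50, 16, 16)
  img3[8, 8] <- 255
  expect_equal(amed_map(img3, cfg)[8, 8], 50)
  expect_equal(namad_map(img3, cfg)[8, 8], 0)
})

test_that("mROR is zero at the median, huge and maximal at an isolated impulse", {
  img <- matrix(50, 16, 16)
  img[8, 8] <- 255
  m <- mror_map(img)
  expect_equal(m[1, 1], 0)                     # pixel equals its AMED
  expect_equal(m[8, 8], 205 / 1e-6)            # epsilon-guarded flat window
  expect_true(m[8, 8] > max(m[-(8 + 7 * 16)])) # strictly above all others
  expect_true(all(is.finite(m)) && all(m >= 0))
})

test_that("sliding-window maps equal the naive per-pixel oracle exactly", {
  for (border in c("reflect", "exclude_partial")) {
    cfg <- robust_config(border = border)
    for (seed in 1:3) {
      img <- random_image(20, 17, seed = 100 + seed)
      ref <- oracle_maps(img, cfg)
      expect_identical(amed_map(img, cfg), ref$amed)
      expect_identical(namad_map(img, cfg), ref$namad)
      expect_identical(mror_map(img, cfg), ref$mror)
    }
  }
})

test_that("mROR is invariant to intensity shifts, and to scaling where the scale is informative", {
  img <- random_image(24, 24, seed = 42)
  m <- mror_map(pmin(img, 248))
  shifted <- mror_map(pmin(img, 248) + 7)
  expect_identical(m, shifted)

  half <- img / 2
  m1 <- mror_map(half)
  m2 <- mror_map(half * 2)
  informative <- namad_map(half) > robust_config()$epsilon
  expect_equal(m1[informative], m2[informative], tolerance = 1e-12)
})

test_that("cluster labels follow the right-closed mROR intervals", {
  vals <- c(3.5, 3.0, 2.5, 2.0, 1.5, 1.0, 0.5, 0.0)
  mror <- matrix(rep(vals, length.out = 16 * 16), 16, 16)
  lab <- cluster_pixels(mror)
  expect_equal(lab[1:8], c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L))
  # exhaustive and mutually exclusive for arbitrary non-negative scores
  rnd <- matrix(rexp(400, rate = 0.5), 20, 20)
  expect_true(all(cluster_pixels(rnd) %in% 1:4))
})

test_that("cluster counts partition the image and respond to noise", {
  img <- matrix(100, 16, 16)
  cc <- cluster_counts(cluster_pixels(mror_map(img)))
  expect_equal(cc$n, c(0L, 0L, 0L, 256L))  # flat image: all least-noisy

  clean <- make_phantom(phantom_spec(height = 64, width = 64, seed = 8))
  noisy <- corrupt(clean, noise_spec("fixed_valued", p = 0.2, seed = 1))$image
  n_clean <- cluster_counts(cluster_pixels(mror_map(clean)))$n
  n_noisy <- cluster_counts(cluster_pixels(mror_map(noisy)))$n
  expect_equal(sum(n_clean), 64 * 64)
  expect_equal(sum(n_noisy), 64 * 64)
  expect_gt(n_noisy[1], n_clean[1])  # noise inflates the most-suspect cluster
})
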