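# Independent brute-force recomputation of the windowed robust statistics,
# written as a naive per-pixel double loop with its own border handling and
# stats::median(), deliberately sharing no code with the package kernels.

oracle_reflect <- function(i, n) {
  while (i < 1L || i > n) {
    i <- if (i < 1L) 1L - i else 2L * n + 1L - i
  }
  i
}

oracle_window <- function(image, r, c, window, border) {
  k <- window %/% 2L
  vals <- c()
  for (dr in -k:k) {
    for (dc in -k:k) {
      rr <- r + dr
      cc <- c + dc
      if (border == "reflect") {
        rr <- oracle_reflect(rr, nrow(image))
        cc <- oracle_reflect(cc, ncol(image))
      } else if (rr < 1L || rr > nrow(image) || cc < 1L || cc > ncol(image)) {
        next
      }
      vals <- c(vals, image[rr, cc])
    }
  }
  vals
}

oracle_maps <- function(image, cfg) {
  nr <- nrow(image)
  nc <- ncol(image)
  amed <- amad <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      y <- oracle_window(image, r, c, cfg$window, cfg$border)
      m <- stats::median(y)
      amed[r, c] <- m
      amad[r, c] <- stats::median(abs(y - m))
    }
  }
  namad <- amad / cfg$amads_constant
  list(amed = amed, amad = amad, namad = namad,
       mror = abs(image - amed) / pmax(namad, cfg$epsilon))
}

# seeded random 8-bit test image (double storage, the package convention)
random_image <- function(nr, nc, seed) {
  withr::with_seed(seed,
    matrix(as.double(sample(0:255, nr * nc, replace = TRUE)), nr, nc))
}

# phantom spec with masses scaled down to fit small test images
small_phantom <- function(n = 32, seed = 1, ...) {
  phantom_spec(height = n, width = n, n_masses = 2,
               mass_radius_range = c(4, 8), n_specks = 4, seed = seed, ...)
}
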