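#' Specify a mammogram-like phantom
#'
#' Defines a synthetic test image emulating the gross structure of a
#' mammogram: a smooth glandular background with a broad illumination dome,
#' a few soft-edged bright blobs standing in for masses, and isolated bright
#' specks standing in for microcalcifications. Phantoms are the package's
#' offline stand-in for real mammograms; they reproduce the features that
#' matter for impulse-noise work (smooth background, soft-edged structures,
#' rare point-like bright detail) without claiming statistical equivalence to
#' breast tissue.
#'
#' @param height,width image size in pixels (each at least 16).
#' @param background_level base intensity of the tissue background.
#' @param gradient_amplitude peak intensity of the smooth illumination dome
#'   added to the background (0 disables it).
#' @param n_masses number of soft-edged bright blobs.
#' @param mass_radius_range length-2 numeric, min and max blob radius in
#'   pixels.
#' @param mass_contrast peak intensity a blob adds above the background.
#' @param n_specks number of bright specks (one pixel plus a faint
#'   4-neighbour halo).
#' @param speck_contrast intensity a speck adds at its centre pixel.
#' @param seed integer seed; the phantom is a pure function of the spec, so
#'   identical specs give bit-identical images.
#' @return an object of class `phantom_spec`.
#' @seealso [make_phantom()]
#' @export
phantom_spec <- function(height = 256L, width = 256L,
                         background_level = 90,
                         gradient_amplitude = 40,
                         n_masses = 3L,
                         mass_radius_range = c(12, 30),
                         mass_contrast = 45,
                         n_specks = 15L,
                         speck_contrast = 70,
                         seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               background_level = background_level,
               gradient_amplitude = gradient_amplitude,
               n_masses = as.integer(n_masses),
               mass_radius_range = as.numeric(mass_radius_range),
               mass_contrast = mass_contrast,
               n_specks = as.integer(n_specks),
               speck_contrast = speck_contrast,
               seed = as.integer(seed))
  if (spec$height < 16L || spec$width < 16L)
    stop("phantom must be at least 16 x 16 pixels", call. = FALSE)
  if (spec$background_level < 0 || spec$background_level > 255)
    stop("background_level must lie in [0, 255]", call. = FALSE)
  if (spec$gradient_amplitude < 0 || spec$n_masses < 0L || spec$n_specks < 0L)
    stop("gradient_amplitude, n_masses and n_specks must be non-negative",
         call. = FALSE)
  if (length(spec$mass_radius_range) != 2L ||
      any(spec$mass_radius_range <= 0) ||
      diff(spec$mass_radius_range) < 0)
    stop("mass_radius_range must be an increasing pair of positive radii",
         call. = FALSE)
  if (spec$n_masses > 0L &&
      2 * max(spec$mass_radius_range) + 2 > min(spec$height, spec$width))
    stop("requested masses do not fit: 2 * max radius + 2 exceeds the ",
         "smaller image dimension", call. = FALSE)
  structure(spec, class = "phantom_spec")
}

#' Generate a mammogram-like phantom image
#'
#' Deterministically renders the phantom described by a [phantom_spec()]:
#' background level, plus a broad Gaussian illumination dome, plus soft-edged
#' super-Gaussian blobs ("masses"), plus one-pixel bright specks with a faint
#' 4-neighbour halo ("microcalcifications"), clipped to `[0, 255]`. The
#' caller's random-number state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return numeric matrix in `[0, 255]`.
#' @examples
#' img <- make_phantom(phantom_spec(height = 64, width = 64, seed = 7))
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  h <- spec$height
  w <- spec$width
  withr::with_seed(spec$seed, {
    img <- matrix(spec$background_level, h, w)
    rr <- row(img)
    cc <- col(img)
    if (spec$gradient_amplitude > 0) {
      cy <- stats::runif(1, 0.3, 0.7) * h
      cx <- stats::runif(1, 0.3, 0.7) * w
      d2 <- ((rr - cy) / h)^2 + ((cc - cx) / w)^2
      img <- img + spec$gradient_amplitude * exp(-d2 / 0.18)
    }
    if (spec$n_masses > 0L) {
      for (i in seq_len(spec$n_masses)) {
        r0 <- stats::runif(1, spec$mass_radius_range[1],
                           spec$mass_radius_range[2])
        my <- stats::runif(1, r0 + 1, h - r0)
        mx <- stats::runif(1, r0 + 1, w - r0)
        d2 <- ((rr - my)^2 + (cc - mx)^2) / r0^2
        img <- img + spec$mass_contrast * exp(-d2^2)  # flat core, soft edge
      }
    }
    if (spec$n_specks > 0L) {
      sy <- sample(2:(h - 1L), spec$n_specks, replace = TRUE)
      sx <- sample(2:(w - 1L), spec$n_specks, replace = TRUE)
      for (i in seq_len(spec$n_specks)) {
        img[sy[i], sx[i]] <- img[sy[i], sx[i]] + spec$speck_contrast
        halo <- 0.35 * spec$speck_contrast
        img[sy[i] - 1L, sx[i]] <- img[sy[i] - 1L, sx[i]] + halo
        img[sy[i] + 1L, sx[i]] <- img[sy[i] + 1L, sx[i]] + halo
        img[sy[i], sx[i] - 1L] <- img[sy[i], sx[i] - 1L] + halo
        img[sy[i], sx[i] + 1L] <- img[sy[i], sx[i] + 1L] + halo
      }
    }
    pmin(pmax(img, 0), 255)
  })
}
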