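#' Specify an impulse-noise corruption process
#'
#' Parameters of the impulse model: each pixel is independently replaced with
#' probability `p`. Under the fixed-valued (salt-and-pepper) model the
#' replacement is `eta_min` or `eta_max` with equal probability; under the
#' random-valued model it is drawn uniformly on `[eta_min, eta_max]` and
#' rounded to an integer intensity. A random-valued replacement may coincide
#' with the original value; the pixel still counts as corrupted — the process,
#' not the outcome, defines corruption.
#'
#' @param kind `"fixed_valued"` (salt-and-pepper) or `"random_valued"`.
#' @param p corruption probability per pixel, in `[0, 1]`.
#' @param eta_min,eta_max permissible replacement range, `0 <= eta_min <
#'   eta_max <= 255`.
#' @param seed integer seed making the corruption reproducible.
#' @param exact_count if `TRUE`, corrupt exactly `round(p * n)` pixels chosen
#'   uniformly at random instead of independent per-pixel Bernoulli draws;
#'   useful for fixed-ratio experiments.
#' @return an object of class `noise_spec`.
#' @seealso [corrupt()]
#' @export
noise_spec <- function(kind = c("fixed_valued", "random_valued"),
                       p = 0.1, eta_min = 0, eta_max = 255,
                       seed = 1L, exact_count = FALSE) {
  kind <- match.arg(kind)
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single probability in [0, 1]", call. = FALSE)
  if (eta_min < 0 || eta_max > 255 || eta_min >= eta_max)
    stop("need 0 <= eta_min < eta_max <= 255", call. = FALSE)
  structure(list(kind = kind, p = p, eta_min = eta_min, eta_max = eta_max,
                 seed = as.integer(seed), exact_count = isTRUE(exact_count)),
            class = "noise_spec")
}

#' Corrupt an image with impulse noise
#'
#' Applies the impulse model of a [noise_spec()] to an image: each pixel is
#' independently replaced with probability `p` (or exactly `round(p * n)`
#' pixels when `exact_count` is set), uncorrupted pixels are bit-identical to
#' the input, and the returned mask marks exactly the replaced pixels — the
#' ground truth for detector evaluation. Fully reproducible from the spec's
#' seed; the caller's random-number state is left untouched.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param spec a [noise_spec()].
#' @return list with elements `image` (the corrupted matrix) and `mask`
#'   (logical matrix, `TRUE` where a pixel was replaced).
#' @examples
#' clean <- make_phantom(phantom_spec(height = 64, width = 64))
#' noisy <- corrupt(clean, noise_spec("fixed_valued", p = 0.2, seed = 9))
#' corruption_rate(noisy$mask)
#' @export
corrupt <- function(image, spec) {
  assert_gray(image)
  if (!inherits(spec, "noise_spec")) stop("spec must be a noise_spec",
                                          call. = FALSE)
  n <- length(image)
  draws <- withr::with_seed(spec$seed, {
    flags <- if (spec$exact_count) {
      k <- as.integer(round(spec$p * n))
      f <- logical(n)
      if (k > 0L) f[sample.int(n, k)] <- TRUE
      f
    } else {
      stats::runif(n) < spec$p
    }
    k <- sum(flags)
    repl <- if (k == 0L) {
      numeric(0)
    } else if (spec$kind == "fixed_valued") {
      ifelse(stats::runif(k) < 0.5, spec$eta_min, spec$eta_max)
    } else {
      # drawn continuously, then rounded to integer intensities (half-up)
      floor(stats::runif(k, spec$eta_min, spec$eta_max) + 0.5)
    }
    list(flags = flags, repl = repl)
  })
  noisy <- image
  storage.mode(noisy) <- "double"
  noisy[draws$flags] <- draws$repl
  list(image = noisy,
       mask = matrix(draws$flags, nrow(image), ncol(image)))
}

#' Fraction of corrupted (or detected) pixels in a mask
#'
#' @param mask logical matrix.
#' @return fraction of `TRUE` entries, in `[0, 1]`.
#' @export
corruption_rate <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask) || anyNA(mask))
    stop("mask must be a logical matrix without missing values",
         call. = FALSE)
  mean(mask)
}
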