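#' Built-in benchmark methods
#'
#' Returns the registry of restoration methods the benchmark harness knows:
#' `"proposed"` (the full detect-then-NL-means pipeline, which also reports
#' its detection mask), `"adaptive_median"` and `"standard_median"`. Each
#' entry is a function of the noisy image returning
#' `list(image = <restored>, mask = <detected mask or NULL>)`; users can
#' extend the list with their own plug-in filters of the same signature.
#'
#' @param det_cfg a [detection_config()] for the proposed pipeline.
#' @param nlm_cfg an [nlm_config()] for the proposed pipeline.
#' @param median_window window side for the standard median baseline.
#' @param adaptive_max_window maximum window for the adaptive median
#'   baseline.
#' @return named list of method functions.
#' @export
benchmark_methods <- function(det_cfg = detection_config(),
                              nlm_cfg = nlm_config(),
                              median_window = 3L,
                              adaptive_max_window = 11L) {
  list(
    proposed = function(noisy) {
      res <- denoise(noisy, det_cfg, nlm_cfg, return_details = TRUE)
      list(image = res$image, mask = res$detection$mask)
    },
    adaptive_median = function(noisy) {
      list(image = adaptive_median(noisy, adaptive_max_window), mask = NULL)
    },
    standard_median = function(noisy) {
      list(image = standard_median(noisy, median_window), mask = NULL)
    }
  )
}

#' Run the corruption / restoration / scoring benchmark
#'
#' For every combination of noise ratio, seed and method: generate the
#' phantom, corrupt it, restore it, and score the restoration. Seeds are
#' shared across methods at each (ratio, seed) cell, so method comparisons
#' are paired on identical noise realizations, and the whole table is
#' bit-reproducible from its arguments.
#'
#' @param spec a [phantom_spec()] describing the clean test image.
#' @param ratios numeric vector of corruption probabilities.
#' @param methods character vector naming entries of `method_registry`.
#' @param seeds integer vector of noise seeds (one benchmark replicate each).
#' @param kind `"random_valued"` or `"fixed_valued"` impulse noise.
#' @param method_registry named list of method functions, by default
#'   [benchmark_methods()].
#' @return a tibble of class `noise_benchmark` with one row per run:
#'   `method`, `kind`, `ratio`, `seed`, `mse`, `psnr` (dB; `Inf` for a
#'   perfect restoration), and `recall` / `fpr` against the ground-truth
#'   corruption mask for methods that report a detection mask (`NA`
#'   otherwise).
#' @seealso [summarize_benchmark()], [plot_benchmark()],
#'   [write_benchmark_csv()]
#' @export
run_benchmark <- function(spec = phantom_spec(),
                          ratios = c(0.1, 0.3, 0.5),
                          methods = c("proposed", "adaptive_median",
                                      "standard_median"),
                          seeds = 1:5,
                          kind = c("random_valued", "fixed_valued"),
                          method_registry = benchmark_methods()) {
  kind <- match.arg(kind)
  unknown <- setdiff(methods, names(method_registry))
  if (length(unknown) > 0L)
    stop("unknown method(s): ", paste(unknown, collapse = ", "),
         "; registered methods are: ",
         paste(names(method_registry), collapse = ", "), call. = FALSE)
  clean <- make_phantom(spec)
  rows <- list()
  for (ratio in ratios) {
    for (seed in seeds) {
      noisy <- corrupt(clean, noise_spec(kind, p = ratio, seed = seed))
      for (m in methods) {
        res <- method_registry[[m]](noisy$image)
        scores <- if (is.null(res$mask)) c(recall = NA_real_, fpr = NA_real_)
                  else detection_scores(res$mask, noisy$mask)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          method = m, kind = kind, ratio = ratio, seed = as.integer(seed),
          mse = mse(clean, res$image), psnr = psnr(clean, res$image),
          recall = scores[["recall"]], fpr = scores[["fpr"]])
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("noise_benchmark", class(out))
  out
}

#' Summarize a benchmark table
#'
#' Mean and standard deviation of PSNR per method and ratio, plus a wide
#' pivot of mean PSNR with one column per noise ratio (the layout of the
#' usual method-comparison tables).
#'
#' @param results a tibble from [run_benchmark()].
#' @return list with `by_cell` (tibble of per-method, per-ratio summaries)
#'   and `psnr_table` (wide tibble, methods x ratios).
#' @export
summarize_benchmark <- function(results) {
  by_cell <- results |>
    dplyr::group_by(.data$method, .data$kind, .data$ratio) |>
    dplyr::summarise(mean_psnr = mean(.data$psnr),
                     sd_psnr = stats::sd(.data$psnr),
                     mean_mse = mean(.data$mse),
                     n = dplyr::n(), .groups = "drop")
  psnr_table <- by_cell |>
    dplyr::mutate(ratio = sprintf("psnr_%g", .data$ratio)) |>
    dplyr::select("method", "ratio", "mean_psnr") |>
    tidyr::pivot_wider(names_from = "ratio", values_from = "mean_psnr")
  list(by_cell = by_cell, psnr_table = psnr_table)
}

#' Write benchmark results to CSV
#'
#' Writes one row per run with the documented columns of [run_benchmark()].
#' Infinite PSNR values (perfect restorations) are written as the sentinel
#' string `"Inf"`, never as a float, so downstream parsers cannot mistake a
#' sentinel for a measurement.
#'
#' @param results a tibble from [run_benchmark()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark_csv <- function(results, path) {
  out <- as.data.frame(results)
  out$psnr <- ifelse(is.infinite(out$psnr), "Inf",
                     format(out$psnr, digits = 10, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Plot mean PSNR against noise ratio per method
#'
#' @param results a tibble from [run_benchmark()].
#' @return a ggplot object.
#' @export
plot_benchmark <- function(results) {
  cell <- summarize_benchmark(results)$by_cell
  ggplot2::ggplot(cell, ggplot2::aes(x = .data$ratio, y = .data$mean_psnr,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "impulse-noise ratio", y = "mean PSNR (dB)",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' @rdname plot_benchmark
#' @param object a `noise_benchmark` tibble.
#' @param ... unused.
#' @export
autoplot.noise_benchmark <- function(object, ...) {
  plot_benchmark(object)
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
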