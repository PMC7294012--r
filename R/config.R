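#' Load pipeline configuration from a YAML file
#'
#' Reads a key-value YAML file with up to six optional top-level sections and
#' returns fully validated configuration objects, with package defaults
#' filling any field (or section) the file omits:
#'
#' \describe{
#'   \item{`phantom`}{fields of [phantom_spec()] — `height`, `width`,
#'     `background_level`, `gradient_amplitude`, `n_masses`,
#'     `mass_radius_range`, `mass_contrast`, `n_specks`, `speck_contrast`,
#'     `seed`.}
#'   \item{`noise`}{fields of [noise_spec()] — `kind`, `p`, `eta_min`,
#'     `eta_max`, `seed`, `exact_count`.}
#'   \item{`stats`}{fields of [robust_config()] — `window`,
#'     `amads_constant`, `epsilon`, `border`.}
#'   \item{`afm`}{fields of [afm_config()] — `initial_window`,
#'     `max_window`, `fuzzy_spread`, `min_clean`, `weight_floor`.}
#'   \item{`detection`}{fields of [detection_config()] —
#'     `coarse_iterations`, `fine_iterations`, `coarse_thresholds`,
#'     `fine_thresholds` (the `stats` and `afm` sections supply its nested
#'     configs).}
#'   \item{`nlm`}{fields of [nlm_config()] — `patch_radius`,
#'     `search_radius`, `bandwidth_h`, `min_clean_fraction`.}
#' }
#'
#' @param path path to a YAML file.
#' @return named list with elements `phantom`, `noise`, `stats`, `afm`,
#'   `detection`, `nlm`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("phantom", "noise", "stats", "afm", "detection", "nlm")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L)
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         "; known sections are: ", paste(known, collapse = ", "),
         call. = FALSE)
  build <- function(section, constructor, extra_args = list()) {
    args <- c(raw[[section]], extra_args)
    do.call(constructor, args)
  }
  stats_cfg <- build("stats", robust_config)
  afm_cfg <- build("afm", afm_config)
  list(
    phantom = build("phantom", phantom_spec),
    noise = build("noise", noise_spec),
    stats = stats_cfg,
    afm = afm_cfg,
    detection = build("detection", detection_config,
                      list(stat_config = stats_cfg, afm_config = afm_cfg)),
    nlm = build("nlm", nlm_config)
  )
}
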