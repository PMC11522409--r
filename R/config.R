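#' Analysis configuration
#'
#' Collects every tunable of the analysis pipeline with its default. The
#' defaults are the values used for embryonic cortical-hippocampal cultures:
#' a 4th-order Butterworth band-pass at 300--3000 Hz with a 50 Hz mains
#' notch, PTSD at 9 noise SDs (7.5 is the usual choice for adult cultures)
#' with 1 ms peak lifetime and 1.6 ms refractory period, logISI bursts of at
#' least 4 spikes with the ISI threshold capped at 100 ms, network bursts
#' requiring 10% of active electrodes, 50 ms correlation bins with a 10-bin
#' maximum lag and a 0.1 edge threshold, 15 ms post-stimulus blanking with
#' 20 ms PSTH bins over a 300 ms window, and a 5 micrometre particle-diameter
#' cut at 2803/2046 micrometres per pixel.
#'
#' @param ... named overrides of any default listed below.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    # filtering
    filter_order = 4, low_cut = 300, high_cut = 3000,
    notch_freq = 50, notch_q = 30, zero_phase = TRUE,
    # SALPA + blanking
    salpa_poly_order = 3, salpa_halfwidth = 0.003, salpa_epoch = 0.3,
    blank_after = 0.015,
    # spike detection (PTSD)
    threshold_k = 9, peak_lifetime = 0.001, refractory = 0.0016,
    noise_sd_method = "mad",
    # burst / network-burst detection
    min_spikes = 4, max_isi = 0.100, bins_per_decade = 10,
    void_threshold = 0.7, smooth_bins = 3, active_rate_min = 0.1,
    nb_fraction = 0.10,
    # dynamics
    ci_bin = 0.050, psth_bin = 0.020, psth_window = 0.300,
    # connectivity & graph
    corr_bin = 0.050, max_lag_bins = 10, edge_threshold = 0.1,
    louvain_gamma = 1, louvain_restarts = 100,
    pagerank_damping = 0.85,
    # particle quantification
    um_per_px = 2803 / 2046, min_diameter = 5, watershed_tolerance = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("analysis_config: unknown parameter(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "analysis_config"
  validate_analysis_config(cfg)
  cfg
}

#' @export
validate_analysis_config <- function(cfg) {
  durs <- c("peak_lifetime", "refractory", "max_isi", "ci_bin", "psth_bin",
            "psth_window", "corr_bin", "blank_after", "salpa_halfwidth",
            "salpa_epoch")
  for (f in durs)
    if (cfg[[f]] <= 0) stop("analysis_config: '", f, "' must be positive")
  if (cfg$nb_fraction <= 0 || cfg$nb_fraction > 1)
    stop("analysis_config: 'nb_fraction' must be in (0, 1]")
  if (cfg$void_threshold <= 0 || cfg$void_threshold >= 1)
    stop("analysis_config: 'void_threshold' must be in (0, 1)")
  if (cfg$low_cut <= 0 || cfg$low_cut >= cfg$high_cut)
    stop("analysis_config: need 0 < low_cut < high_cut")
  if (cfg$threshold_k <= 0) stop("analysis_config: 'threshold_k' must be positive")
  if (cfg$refractory < cfg$peak_lifetime)
    stop("analysis_config: 'refractory' must be >= 'peak_lifetime'")
  if (cfg$min_spikes < 2) stop("analysis_config: 'min_spikes' must be >= 2")
  if (cfg$um_per_px <= 0) stop("analysis_config: 'um_per_px' must be positive")
  invisible(cfg)
}

#' Read / write an analysis configuration
#'
#' Configurations are stored as flat YAML `key: value` files using exactly
#' the parameter names of [analysis_config]; the round trip is lossless.
#'
#' @param path file path.
#' @rdname config_io
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' @param config an [analysis_config].
#' @rdname config_io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
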