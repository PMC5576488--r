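#' Default pipeline configuration
#'
#' Returns the full nested configuration used by every stage. Values mirror
#' the analysis conventions of awake-SWR studies: a 4 cm/s movement
#' threshold, a 150-250 Hz ripple band with a 4 ms envelope smoothing
#' kernel and a 99.99th-percentile mode-mirrored noise threshold, 2 cm
#' spatial bins with sigma = 2 cm / 12 cm extent rate-map smoothing, a
#' 3 Hz immobility well-rate criterion with a 200-spike minimum, 10 ms
#' correlogram bins, 5000 coactivity permutations and 1000 circular
#' permutations for the PFC modulation test. The \code{generator} section
#' parameterises the synthetic session (see \code{\link{generateSession}}).
#'
#' @return A nested named list.
#' @examples
#' cfg <- defaultConfig()
#' cfg$behavior$speed_threshold_cm_s
#' @export
defaultConfig <- function() {
  list(
    behavior = list(
      speed_threshold_cm_s = 4,
      immobility_threshold_cm_s = 1,
      speed_smoothing_sigma_s = 0.25,
      occupancy_bin_cm = 2
    ),
    swr_detection = list(
      ripple_band = c(150, 250),
      envelope_smoothing_sigma_ms = 4,
      noise_percentile = 99.99,
      min_event_ms = 20,
      mode_bins = 200,
      use_power = FALSE,
      spectrogram_window_s = 0.1,
      spectrogram_step_s = 0.01
    ),
    place_coding = list(
      interneuron_width_ms = 0.4,
      interneuron_rate_hz = 10,
      iap_rate_threshold_hz = 3,
      min_spikes = 200,
      ratemap_sigma_cm = 2,
      ratemap_extent_cm = 12,
      coverage_rate_fraction = 0.2,
      coverage_min_occupancy_s = 0.1
    ),
    temporal = list(
      correlogram_bin_s = 0.01,
      near_window_s = 0.05,
      far_window_s = 3.3,
      peth_window_s = 5,
      peth_bin_s = 0.1,
      peth_smoothing_sigma_s = 0.1,
      coincidence_bin_s = 0.1,
      coincidence_window_s = 20,
      min_coincidences = 100
    ),
    swr_content = list(
      n_permutations = 5000,
      eligibility_max_lag_s = 3.3
    ),
    pfc = list(
      min_rate_hz = 1,
      n_permutations = 1000,
      peth_halfwindow_s = 0.5,
      peth_bin_s = 0.01,
      peth_smoothing_sigma_s = 0.02,
      alpha = 0.05,
      min_events = 10
    ),
    generator = list(
      n_wells = 4,
      session_length_s = 1800,
      mean_bout_s = 6.6,
      position_rate_hz = 30,
      arena_cm = 100,
      well_radius_cm = 10,
      n_map = 20,
      n_iap = 10,
      n_pfc = 16,
      field_peak_hz = 20,
      field_sigma_cm = 12,
      iap_rate_hz = 5,
      swr_rate_hz = 0.22,
      swr_duration_mu_log = log(0.08),
      swr_duration_sigma_log = 0.4,
      iap_duration_scale = 1,
      ripple_freq_hz = 200,
      ripple_snr = 5,
      lfp_sample_rate_hz = 1500,
      lfp_noise_sd_uv = 50,
      n_channels = 4,
      class_probs = c(0.67, 0.26, 0.07),
      participation_prob = 0.3,
      content_spike_mean = 1.5,
      content_guard_s = 0.075,
      iap_early_offset_s = 0,
      pfc_baseline_hz = 4,
      pfc_gain_excited = 3,
      pfc_gain_inhibited = 0.15,
      pfc_behavior_gain = 1.5,
      theta_freq_hz = 8,
      theta_depth = 0.5,
      min_event_gap_s = 0.15
    )
  )
}

mergeConfig <- function(defaults, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key '%s'", full))
    if (is.list(defaults[[key]])) {
      if (!is.list(override[[key]]))
        stop(sprintf("configuration key '%s' must be a section", full))
      defaults[[key]] <- mergeConfig(defaults[[key]], override[[key]], full)
    } else {
      v <- override[[key]]
      if (is.list(v)) v <- unlist(v)
      if (length(defaults[[key]]) > 1L && length(v) != length(defaults[[key]]))
        stop(sprintf("configuration key '%s' must have %d values", full,
                     length(defaults[[key]])))
      storage.mode(v) <- storage.mode(defaults[[key]])
      defaults[[key]] <- v
    }
  }
  defaults
}

validateConfig <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("configuration out of range: ", what)
  chk(cfg$behavior$speed_threshold_cm_s > 0, "behavior.speed_threshold_cm_s must be > 0")
  chk(cfg$behavior$occupancy_bin_cm > 0, "behavior.occupancy_bin_cm must be > 0")
  b <- cfg$swr_detection$ripple_band
  chk(length(b) == 2 && b[1] > 0 && b[2] > b[1], "swr_detection.ripple_band")
  chk(cfg$swr_detection$min_event_ms > 0, "swr_detection.min_event_ms must be > 0")
  chk(cfg$swr_detection$noise_percentile > 50 && cfg$swr_detection$noise_percentile < 100,
      "swr_detection.noise_percentile must be in (50, 100)")
  g <- cfg$generator
  chk(g$lfp_sample_rate_hz >= 1000, "generator.lfp_sample_rate_hz must be >= 1000")
  chk(g$position_rate_hz > 0, "generator.position_rate_hz must be > 0")
  chk(abs(sum(g$class_probs) - 1) < 1e-8 && all(g$class_probs >= 0) &&
        all(g$class_probs <= 1), "generator.class_probs must be probabilities summing to 1")
  chk(g$participation_prob >= 0 && g$participation_prob <= 1,
      "generator.participation_prob must be in [0, 1]")
  chk(all(c(g$iap_rate_hz, g$swr_rate_hz, g$pfc_baseline_hz, g$field_peak_hz) >= 0),
      "generator rates must be >= 0")
  chk(g$ripple_snr > 0, "generator.ripple_snr must be > 0")
  chk(g$mean_bout_s > 0, "generator.mean_bout_s must be > 0")
  chk(cfg$pfc$n_permutations >= 1, "pfc.n_permutations must be >= 1")
  chk(cfg$swr_content$n_permutations >= 1, "swr_content.n_permutations must be >= 1")
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a (possibly partial) nested YAML file, fills every absent key with
#' its default from \code{\link{defaultConfig}}, rejects unknown keys and
#' checks ranges. An empty file yields the full default configuration.
#'
#' @param path path to a YAML file, or \code{NULL} for pure defaults.
#' @return Validated nested configuration list.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("swr_detection:\n  min_event_ms: 30", f)
#' loadConfig(f)$swr_detection$min_event_ms
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    override <- yaml::read_yaml(path)
    if (!is.null(override)) {
      if (!is.list(override)) stop("configuration file must contain a mapping")
      cfg <- mergeConfig(cfg, override)
    }
  }
  validateConfig(cfg)
}
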