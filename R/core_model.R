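#' Construct a multichannel recording
#'
#' The basic data container: a channels x samples matrix of field
#' amplitudes with its sampling rate. All cleaning functions operate on
#' this canonical orientation; the I/O layer converts on read.
#'
#' @param data Numeric matrix, channels x samples.
#' @param srate Sampling rate in Hz (> 0).
#' @param channel_labels Optional character vector, one label per channel.
#' @return An object of class `"recording"` with elements `data`, `srate`,
#'   `channel_labels`.
#' @examples
#' rec <- recording(matrix(rnorm(2 * 500), 2), srate = 100)
#' n_channels(rec)
#' @export
recording <- function(data, srate, channel_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(srate) || length(srate) != 1 || !is.finite(srate) || srate <= 0) {
    zap_abort("zap_invalid_recording", "srate must be a single positive number")
  }
  if (nrow(data) < 2) {
    zap_abort("zap_invalid_recording",
              "at least 2 channels are required for spatial filtering (got %d)",
              nrow(data))
  }
  if (!all(is.finite(data))) {
    zap_abort("zap_invalid_recording", "recording contains non-finite values")
  }
  if (!is.null(channel_labels)) {
    channel_labels <- as.character(channel_labels)
    if (length(channel_labels) != nrow(data)) {
      zap_abort("zap_invalid_recording",
                "channel_labels length (%d) does not match channel count (%d)",
                length(channel_labels), nrow(data))
    }
  }
  structure(list(data = data, srate = srate, channel_labels = channel_labels),
            class = "recording")
}

#' @rdname recording
#' @param rec A `recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname recording
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$srate

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              n_channels(x), n_samples(x), x$srate, duration_s(x)))
  invisible(x)
}

#' Convert a 10*log10 power difference to a linear power ratio
#'
#' Detection thresholds are expressed in 10*log10 units of power spectral
#' density; this maps such a difference back to a fold change in power.
#' A difference of 4 corresponds to a ~2.5-fold increase, 1.76 to ~1.5x.
#'
#' @param delta Difference in 10*log10 units (dB of power).
#' @return Linear power ratio `10^(delta/10)`.
#' @examples
#' db_to_power_ratio(4)    # ~2.5
#' db_to_power_ratio(1.76) # ~1.5
#' @export
db_to_power_ratio <- function(delta) {
  if (!all(is.finite(delta))) zap_abort("zap_invalid_argument", "delta must be finite")
  10^(delta / 10)
}

#' Cleaning configuration with its documented defaults
#'
#' Every tunable of the adaptive cleaning procedure, each defaulting to the
#' value the algorithm was calibrated with. Pass overrides as named
#' arguments; unknown names are rejected.
#'
#' @param noisefreqs Numeric vector of noise frequencies (Hz) to clean.
#'   Empty (the default) means detect automatically.
#' @param minfreq,maxfreq Search range (Hz) for automatic detection.
#' @param adaptive_nremove Use the iterative outlier detector to pick the
#'   number of removed components per chunk.
#' @param fixed_nremove Minimum (or, with `adaptive_nremove = FALSE`, exact)
#'   number of components removed per chunk.
#' @param detection_winsize Width (Hz) of the detection window whose outer
#'   thirds define the center power.
#' @param coarse_freq_detect_power_diff Threshold (10*log10 units) above the
#'   center power for a bin to count as a noise peak.
#' @param coarse_freq_detect_lower_power_diff Threshold (10*log10 units)
#'   marking the end of the peak region.
#' @param search_individual_noise Detect each chunk's own peak frequency.
#' @param freq_detect_mult_fine Multiplier on the quantile deviation for the
#'   fine (too-weak / too-strong) thresholds.
#' @param detailed_freq_bounds_upper Band (Hz, relative to the noise
#'   frequency) checked for residual peaks.
#' @param detailed_freq_bounds_lower Band (Hz, relative) checked for an
#'   introduced notch.
#' @param max_proportion_above_upper,max_proportion_below_lower Tolerated
#'   proportion of band bins beyond the fine thresholds.
#' @param noise_comp_detect_sigma Initial SD multiplier of the iterative
#'   component-outlier detector.
#' @param adaptive_sigma Adapt the SD multiplier when cleaning is too
#'   weak/strong.
#' @param min_sigma,max_sigma Bounds for the adapted SD multiplier.
#' @param chunk_length Fixed chunk length in seconds; 0 = adaptive
#'   segmentation from covariance stationarity.
#' @param min_chunk_length Minimum chunk length (s) for adaptive
#'   segmentation.
#' @param win_size_complete_spectrum Welch window in samples for the
#'   full-recording spectrum; 0 = auto (srate x chunk length).
#' @param nkeep PCA dimension kept inside the spatial decomposition;
#'   0 = no reduction.
#' @param plot_results Produce the per-frequency diagnostic figure.
#' @return An object of class `"zap_config"` (a named list).
#' @seealso [validate_config()], [zap_clean()]
#' @export
zap_config <- function(noisefreqs = numeric(0),
                       minfreq = 17,
                       maxfreq = 99,
                       adaptive_nremove = TRUE,
                       fixed_nremove = 1,
                       detection_winsize = 6,
                       coarse_freq_detect_power_diff = 4,
                       coarse_freq_detect_lower_power_diff = 1.76,
                       search_individual_noise = TRUE,
                       freq_detect_mult_fine = 2,
                       detailed_freq_bounds_upper = c(-0.05, 0.05),
                       detailed_freq_bounds_lower = c(-0.4, 0.1),
                       max_proportion_above_upper = 0.005,
                       max_proportion_below_lower = 0.005,
                       noise_comp_detect_sigma = 3,
                       adaptive_sigma = TRUE,
                       min_sigma = 2.5,
                       max_sigma = 4,
                       chunk_length = 0,
                       min_chunk_length = 30,
                       win_size_complete_spectrum = 0,
                       nkeep = 0,
                       plot_results = TRUE) {
  cfg <- as.list(environment())
  structure(cfg, class = "zap_config")
}

#' @rdname zap_config
#' @export
default_config <- function() zap_config()

#' @export
print.zap_config <- function(x, ...) {
  cat("<zap_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-36s %s\n", nm,
                if (length(v) == 0) "(empty)" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' Validate a configuration against a recording and fill auto values
#'
#' Resolves `win_size_complete_spectrum = 0` to `srate x chunk_length`
#' (or `srate x min_chunk_length` under adaptive chunking), checks field
#' consistency and that at least one chunk fits into the recording.
#'
#' @param cfg A [zap_config()].
#' @param rec A [recording()].
#' @return The normalized `zap_config`.
#' @export
validate_config <- function(cfg, rec) {
  stopifnot(inherits(cfg, "zap_config"), inherits(rec, "recording"))
  bad <- function(field, why) {
    zap_abort("zap_invalid_config", "invalid config field '%s': %s", field, why)
  }
  if (cfg$minfreq >= cfg$maxfreq) bad("minfreq", "minfreq must be < maxfreq")
  if (cfg$detection_winsize <= 0) bad("detection_winsize", "must be > 0")
  if (cfg$fixed_nremove < 0) bad("fixed_nremove", "must be >= 0")
  if (cfg$min_sigma > cfg$noise_comp_detect_sigma ||
      cfg$noise_comp_detect_sigma > cfg$max_sigma) {
    bad("noise_comp_detect_sigma",
        "must satisfy min_sigma <= noise_comp_detect_sigma <= max_sigma")
  }
  if (cfg$chunk_length < 0) bad("chunk_length", "must be >= 0")
  if (cfg$min_chunk_length <= 0) bad("min_chunk_length", "must be > 0")
  if (cfg$freq_detect_mult_fine < 0) bad("freq_detect_mult_fine", "must be >= 0")
  if (length(cfg$detailed_freq_bounds_upper) != 2 ||
      diff(cfg$detailed_freq_bounds_upper) <= 0) {
    bad("detailed_freq_bounds_upper", "must be an increasing interval")
  }
  if (length(cfg$detailed_freq_bounds_lower) != 2 ||
      diff(cfg$detailed_freq_bounds_lower) <= 0) {
    bad("detailed_freq_bounds_lower", "must be an increasing interval")
  }
  if (cfg$nkeep < 0) bad("nkeep", "must be >= 0")
  if (any(cfg$noisefreqs <= 0) || any(cfg$noisefreqs >= rec$srate / 2)) {
    bad("noisefreqs", "must lie strictly between 0 and Nyquist")
  }
  effective_chunk <- if (cfg$chunk_length > 0) cfg$chunk_length else cfg$min_chunk_length
  if (n_samples(rec) < effective_chunk * rec$srate) {
    zap_abort("zap_recording_too_short",
              "recording (%.1f s) is shorter than the minimum chunk length (%g s)",
              duration_s(rec), effective_chunk)
  }
  if (cfg$win_size_complete_spectrum == 0) {
    cfg$win_size_complete_spectrum <- round(rec$srate * effective_chunk)
  }
  if (cfg$win_size_complete_spectrum > n_samples(rec)) {
    cfg$win_size_complete_spectrum <- n_samples(rec)
  }
  cfg
}

# Externally documented spellings of the configuration fields, used in the
# JSON config/report documents and as CLI flag names so stored configs can
# be cross-referenced against the published parameter list.
config_name_map <- c(
  noisefreqs = "noisefreqs",
  minfreq = "minfreq",
  maxfreq = "maxfreq",
  adaptive_nremove = "adaptiveNremove",
  fixed_nremove = "fixedNremove",
  detection_winsize = "detectionWinsize",
  coarse_freq_detect_power_diff = "coarseFreqDetectPowerDiff",
  coarse_freq_detect_lower_power_diff = "coarseFreqDetectLowerPowerDiff",
  search_individual_noise = "searchIndividualNoise",
  freq_detect_mult_fine = "freqDetectMultFine",
  detailed_freq_bounds_upper = "detailedFreqBoundsUpper",
  detailed_freq_bounds_lower = "detailedFreqBoundsLower",
  max_proportion_above_upper = "maxProportionAboveUpper",
  max_proportion_below_lower = "maxProportionBelowLower",
  noise_comp_detect_sigma = "noiseCompDetectSigma",
  adaptive_sigma = "adaptiveSigma",
  min_sigma = "minsigma",
  max_sigma = "maxsigma",
  chunk_length = "chunkLength",
  min_chunk_length = "minChunkLength",
  win_size_complete_spectrum = "winSizeCompleteSpectrum",
  nkeep = "nkeep",
  plot_results = "plotResults")

#' Serialize / restore a configuration
#'
#' The configuration round-trips through a plain JSON document so a
#' completed cleaning can be replicated exactly from its stored config.
#' Field names in the document use the externally documented camel-case
#' spellings; `read_config` accepts either spelling.
#'
#' @param cfg A `zap_config`.
#' @param path File path to write to / read from.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `zap_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "zap_config"))
  out <- unclass(cfg)
  names(out) <- config_name_map[names(out)]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rev_map <- stats::setNames(names(config_name_map), config_name_map)
  ext <- names(raw) %in% names(rev_map)
  names(raw)[ext] <- rev_map[names(raw)[ext]]
  defaults <- zap_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    zap_abort("zap_invalid_config", "unknown config field(s): %s",
              paste(unknown, collapse = ", "))
  }
  raw$noisefreqs <- as.numeric(raw$noisefreqs)
  do.call(zap_config, raw)
}
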