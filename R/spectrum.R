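#' Welch log-power spectrum of a recording
#'
#' Averaged-periodogram spectral density per channel (Hann taper, 50%
#' overlap, constant detrend per segment), transformed to 10*log10 units.
#' The across-channel arithmetic mean of the log spectra is the log of the
#' geometric mean of the linear spectra, which is less driven by outlier
#' channels than the arithmetic mean and is the curve all detectors
#' operate on.
#'
#' @param rec A [recording()].
#' @param window_samples Welch segment length in samples; also sets the
#'   frequency resolution `srate / window_samples`.
#' @return An object of class `"spectrum_estimate"`: `freqs` (Hz, ascending),
#'   `log_psd` (channels x freqs, 10*log10 of PSD in power/Hz),
#'   `mean_log_psd`, plus `srate` and `window_samples`.
#' @export
welch_log_spectrum <- function(rec, window_samples) {
  stopifnot(inherits(rec, "recording"))
  window_samples <- as.integer(round(window_samples))
  ns <- n_samples(rec)
  if (window_samples > ns) {
    zap_abort("zap_window_too_long",
              "Welch window (%d samples) exceeds recording length (%d)",
              window_samples, ns)
  }
  if (window_samples < 8) {
    zap_abort("zap_invalid_argument", "Welch window too short (%d samples)",
              window_samples)
  }
  n <- window_samples
  win <- hann_window(n)
  u <- sum(win^2)                       # window power for density scaling
  hop <- max(1L, n %/% 2L)
  starts <- seq(1L, ns - n + 1L, by = hop)
  nfreq <- n %/% 2L + 1L
  psd <- matrix(0, nrow = n_channels(rec), ncol = nfreq)
  for (s in starts) {
    seg <- rec$data[, s:(s + n - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)          # constant detrend
    seg <- seg * rep(win, each = nrow(seg))
    ft <- stats::mvfft(t(seg))          # n x channels
    p <- Mod(ft[1:nfreq, , drop = FALSE])^2
    # one-sided density: double everything but DC and (for even n) Nyquist
    p[2:(nfreq - 1L), ] <- 2 * p[2:(nfreq - 1L), ]
    if (n %% 2L == 1L) p[nfreq, ] <- 2 * p[nfreq, ]
    psd <- psd + t(p)
  }
  psd <- psd / (length(starts) * u * rec$srate)
  log_psd <- 10 * log10(pmax(psd, .Machine$double.xmin))
  freqs <- (0:(nfreq - 1L)) * rec$srate / n
  structure(list(freqs = freqs,
                 log_psd = log_psd,
                 mean_log_psd = colMeans(log_psd),
                 srate = rec$srate,
                 window_samples = n),
            class = "spectrum_estimate")
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> %d channels, %d bins, %.4g Hz resolution\n",
              nrow(x$log_psd), length(x$freqs), x$freqs[2] - x$freqs[1]))
  invisible(x)
}

# Indices of the bins of a detection window of width `winsize` Hz centered
# on frequency f, split into thirds. Errors if the window leaves the grid.
detection_window_bins <- function(freqs, f, winsize) {
  lo <- f - winsize / 2
  hi <- f + winsize / 2
  if (lo < freqs[1] - 1e-9 || hi > freqs[length(freqs)] + 1e-9) {
    zap_abort("zap_window_out_of_range",
              "detection window [%g, %g] Hz outside spectrum range [%g, %g]",
              lo, hi, freqs[1], freqs[length(freqs)])
  }
  idx <- which(freqs >= lo - 1e-9 & freqs <= hi + 1e-9)
  nb <- length(idx)
  third <- nb %/% 3L
  if (third < 1L) {
    zap_abort("zap_window_out_of_range",
              "detection window around %g Hz covers too few bins (%d)", f, nb)
  }
  list(all = idx,
       left = idx[1:third],
       right = idx[(nb - third + 1L):nb])
}

#' Center power of the detection window around a frequency
#'
#' Mean of the log-PSD over the left and right thirds of a window of
#' `detection_winsize` Hz centered on `f`; the middle third (the putative
#' peak region) is excluded so a noise peak does not inflate its own
#' baseline.
#'
#' @param spec A `spectrum_estimate` (its `mean_log_psd` is used).
#' @param f Center frequency (Hz).
#' @param cfg A [zap_config()] (for `detection_winsize`).
#' @return Center power in 10*log10 units.
#' @export
center_power <- function(spec, f, cfg = zap_config()) {
  b <- detection_window_bins(spec$freqs, f, cfg$detection_winsize)
  mean(spec$mean_log_psd[c(b$left, b$right)])
}

#' Coarse detection of the next outlier (noise) frequency
#'
#' Scans the mean log spectrum from `search_min` upward with a moving
#' detection window. The first bin exceeding its center power by more than
#' `coarse_freq_detect_power_diff` stops the search; the detection is then
#' widened to the contiguous region whose excess over the center power
#' stays above `coarse_freq_detect_lower_power_diff`, and the frequency of
#' the maximum within that region is returned.
#'
#' @param spec A `spectrum_estimate`.
#' @param search_min,search_max Search range in Hz.
#' @param cfg A [zap_config()].
#' @return The detected frequency (Hz), or `NULL` if no bin qualifies.
#' @export
detect_next_noise_frequency <- function(spec, search_min = NULL,
                                        search_max = NULL, cfg = zap_config()) {
  if (is.null(search_min)) search_min <- cfg$minfreq
  if (is.null(search_max)) search_max <- cfg$maxfreq
  freqs <- spec$freqs
  half <- cfg$detection_winsize / 2
  lo_ok <- freqs[1] + half
  hi_ok <- freqs[length(freqs)] - half
  smin <- max(search_min, lo_ok)
  smax <- min(search_max, hi_ok)
  cand <- which(freqs >= smin & freqs <= smax)
  if (length(cand) == 0 || search_min >= search_max) {
    zap_abort("zap_empty_search_range",
              "no spectrum bins in search range [%g, %g] Hz", search_min, search_max)
  }
  curve <- spec$mean_log_psd
  excess_at <- function(i) {
    b <- detection_window_bins(freqs, freqs[i], cfg$detection_winsize)
    curve[i] - mean(curve[c(b$left, b$right)])
  }
  for (i in cand) {
    if (excess_at(i) > cfg$coarse_freq_detect_power_diff) {
      # widen to the contiguous region above the lower threshold
      left <- i
      while (left - 1L >= cand[1] &&
             excess_at(left - 1L) > cfg$coarse_freq_detect_lower_power_diff) {
        left <- left - 1L
      }
      right <- i
      while (right + 1L <= cand[length(cand)] &&
             excess_at(right + 1L) > cfg$coarse_freq_detect_lower_power_diff) {
        right <- right + 1L
      }
      region <- left:right
      peak <- region[which.max(curve[region])]
      return(freqs[peak])
    }
  }
  NULL
}

#' Fine threshold around a target frequency
#'
#' A robust deviation measure for the spectrum around `f`: the mean of the
#' lower 5% quantiles of the log PSD in the left and right thirds of the
#' detection window, subtracted from the center power. SD and MAD are
#' avoided because outlier peaks drive them upward. Thresholds are
#' center +/- `freq_detect_mult_fine` x deviation.
#'
#' @inheritParams center_power
#' @return A list of class `"fine_threshold"`: `center_power`, `deviation`,
#'   `upper`, `lower`.
#' @export
fine_threshold <- function(spec, f, cfg = zap_config()) {
  b <- detection_window_bins(spec$freqs, f, cfg$detection_winsize)
  curve <- spec$mean_log_psd
  ctr <- mean(curve[c(b$left, b$right)])
  q <- mean(c(stats::quantile(curve[b$left], 0.05, names = FALSE, type = 7),
              stats::quantile(curve[b$right], 0.05, names = FALSE, type = 7)))
  dev <- ctr - q
  structure(list(center_power = ctr,
                 deviation = dev,
                 upper = ctr + cfg$freq_detect_mult_fine * dev,
                 lower = ctr - cfg$freq_detect_mult_fine * dev),
            class = "fine_threshold")
}

#' Per-chunk peak search and noise-presence test
#'
#' Finds the peak of the chunk's mean log spectrum within the band
#' `f_target + detailed_freq_bounds_upper` (default +/- 0.05 Hz) and flags
#' the chunk as carrying the noise artifact when the peak log PSD exceeds
#' the chunk's own upper fine threshold.
#'
#' @param chunk_spec `spectrum_estimate` of the chunk.
#' @param f_target Target noise frequency (Hz) from the full recording.
#' @param cfg A [zap_config()].
#' @return List: `f_peak` (Hz), `present` (logical), `peak_power`,
#'   `threshold` (the `fine_threshold` used).
#' @export
detect_chunk_peak <- function(chunk_spec, f_target, cfg = zap_config()) {
  band <- f_target + cfg$detailed_freq_bounds_upper
  idx <- which(chunk_spec$freqs >= band[1] - 1e-9 & chunk_spec$freqs <= band[2] + 1e-9)
  if (length(idx) == 0) {
    zap_abort("zap_resolution_too_coarse",
              "no spectrum bin falls in [%g, %g] Hz; chunk resolution %g Hz too coarse",
              band[1], band[2], chunk_spec$freqs[2] - chunk_spec$freqs[1])
  }
  curve <- chunk_spec$mean_log_psd
  peak <- idx[which.max(curve[idx])]
  thr <- fine_threshold(chunk_spec, f_target, cfg)
  list(f_peak = chunk_spec$freqs[peak],
       present = curve[peak] > thr$upper,
       peak_power = curve[peak],
       threshold = thr)
}
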