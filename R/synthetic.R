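# Ground-truthed synthetic recordings: 1/f ("pink") background activity
# plus spatially projected sinusoidal noise sources that may drift in
# frequency, vary in amplitude, switch topography, or be active only part
# of the time -- the statistical structure the cleaning algorithm assumes.

#' Pink (1/f) multichannel background
#'
#' Each channel is an independent Gaussian process with a 1/f power
#' spectrum, generated by frequency-domain shaping of white noise
#' (amplitude profile `f^(-1/2)`, DC removed) and standardized to zero
#' mean, unit variance. Deterministic given the seed.
#'
#' @param n_channels Number of channels (>= 2).
#' @param duration_s Duration in seconds.
#' @param srate Sampling rate (Hz).
#' @param seed Integer seed.
#' @return A [recording()].
#' @export
pink_background <- function(n_channels, duration_s, srate, seed = 1) {
  ns <- round(duration_s * srate)
  data <- with_seed(seed, {
    out <- matrix(0, n_channels, ns)
    freqs <- c(0, pmin(1:(ns - 1), ns - (1:(ns - 1)))) * srate / ns
    shape <- c(0, 1 / sqrt(freqs[-1]))
    for (ch in seq_len(n_channels)) {
      white <- stats::rnorm(ns)
      x <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE)) / ns
      out[ch, ] <- (x - mean(x)) / stats::sd(x)
    }
    out
  })
  recording(data, srate)
}

#' Specify an oscillatory noise source
#'
#' @param freq Frequency trajectory: a single Hz value, or a length-2
#'   vector `c(from, to)` for a linear drift over the active interval.
#' @param amplitude Amplitude (field units per unit topography weight);
#'   a single value or length-2 `c(from, to)` for a linear ramp.
#' @param topography Channel-weight vector, or a matrix with one column
#'   per topography segment when the topography switches.
#' @param active_interval `c(start, end)` in seconds (`NULL` = whole
#'   recording).
#' @param topo_change_points Seconds at which the topography switches to
#'   the next column of `topography`.
#' @return A `"noise_source_spec"` list.
#' @export
noise_source_spec <- function(freq, amplitude = 1, topography,
                              active_interval = NULL,
                              topo_change_points = numeric(0)) {
  topography <- as.matrix(topography)
  if (ncol(topography) != length(topo_change_points) + 1L) {
    zap_abort("zap_invalid_argument",
              "need one topography column per segment (%d change points -> %d columns)",
              length(topo_change_points), length(topo_change_points) + 1L)
  }
  if (all(topography == 0)) {
    zap_abort("zap_invalid_argument", "topography must be non-zero")
  }
  structure(list(freq = freq, amplitude = amplitude, topography = topography,
                 active_interval = active_interval,
                 topo_change_points = topo_change_points),
            class = "noise_source_spec")
}

#' Mix noise sources onto a clean recording
#'
#' Each source contributes
#' `amplitude(t) * sin(2 * pi * integral(freq) + phase)` projected through
#' its (possibly switching) topography; the phase is drawn once per source
#' from the seeded generator.
#'
#' @param clean A [recording()] (e.g. from [pink_background()]).
#' @param specs A list of [noise_source_spec()]s (or a single one).
#' @param seed Integer seed for the phases.
#' @return A `"synthetic_truth"` list: `clean`, `noise`, `combined`
#'   (recordings with `combined = clean + noise` exactly), `specs`, `seed`.
#' @export
add_noise_sources <- function(clean, specs, seed = 1) {
  stopifnot(inherits(clean, "recording"))
  if (inherits(specs, "noise_source_spec")) specs <- list(specs)
  ns <- n_samples(clean)
  srate <- clean$srate
  nyq <- srate / 2
  noise <- matrix(0, n_channels(clean), ns)
  phases <- with_seed(seed, stats::runif(length(specs), 0, 2 * pi))
  t_s <- (seq_len(ns) - 1L) / srate
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    if (any(sp$freq <= 0) || any(sp$freq >= nyq)) {
      zap_abort("zap_spec_out_of_band",
                "source frequency outside (0, %g) Hz", nyq)
    }
    if (nrow(sp$topography) != n_channels(clean)) {
      zap_abort("zap_invalid_argument",
                "topography has %d weights for %d channels",
                nrow(sp$topography), n_channels(clean))
    }
    act <- if (is.null(sp$active_interval)) c(0, ns / srate) else sp$active_interval
    on <- t_s >= act[1] & t_s < act[2]
    if (!any(on)) next
    tt <- t_s[on]
    frac <- (tt - tt[1]) / max(tt[length(tt)] - tt[1], 1 / srate)
    f_t <- if (length(sp$freq) == 2) sp$freq[1] + frac * diff(sp$freq) else rep(sp$freq, length(tt))
    a_t <- if (length(sp$amplitude) == 2) sp$amplitude[1] + frac * diff(sp$amplitude) else rep(sp$amplitude, length(tt))
    phase <- phases[si] + 2 * pi * cumsum(f_t) / srate
    s <- a_t * sin(phase)
    # per-sample topography segment
    seg <- findInterval(tt, sp$topo_change_points) + 1L
    for (g in unique(seg)) {
      cols <- which(seg == g)
      noise[, which(on)[cols]] <- noise[, which(on)[cols]] +
        sp$topography[, g] %o% s[cols]
    }
  }
  combined <- recording(clean$data + noise, srate, clean$channel_labels)
  structure(list(clean = clean,
                 noise = recording(noise + 0, srate, clean$channel_labels),
                 combined = combined,
                 specs = specs,
                 seed = seed),
            class = "synthetic_truth")
}

# Solve for the sinusoid amplitude that yields a target noise/surroundings
# ratio on a given background: band power is affine in amplitude^2, so one
# probe measurement at a = 1 determines the scaling.
calibrate_amplitude <- function(clean, make_truth, f, target_ratio,
                                cfg = zap_config()) {
  win <- round(clean$srate * cfg$min_chunk_length)
  spec0 <- welch_log_spectrum(clean, win)
  band <- f + cfg$detailed_freq_bounds_upper
  idx <- which(spec0$freqs >= band[1] - 1e-9 & spec0$freqs <= band[2] + 1e-9)
  band_power <- function(spec) mean(10^(spec$mean_log_psd[idx] / 10))
  ctr <- 10^(center_power(spec0, f, cfg) / 10)
  p0 <- band_power(spec0)
  probe <- make_truth(1)
  p1 <- band_power(welch_log_spectrum(probe$combined, win))
  coef <- max(p1 - p0, .Machine$double.eps)
  a2 <- (target_ratio * ctr - p0) / coef
  sqrt(max(a2, 0))
}

#' Deterministic catalog of ground-truthed fixtures
#'
#' Named synthetic scenarios spanning the regimes the algorithm must
#' handle: a stationary 50 Hz source at an EEG-like contamination level
#' (noise/surroundings ratio ~6), a slowly drifting peak
#' (49.95 -> 50.05 Hz), a source whose topography switches abruptly at
#' 100 s and 200 s, a two-frequency scenario (50 Hz throughout plus 21 Hz
#' in the second half only), an MEG-like very strong source (64 channels,
#' ratio ~500), and a noise-free control. Amplitudes are calibrated
#' against the generated background by a one-shot linear solve in noise
#' power. All fixtures are 300 s at 250 Hz and regenerate bit-identically
#' from `(name, seed)`.
#'
#' @param names Which fixtures to build (default: all).
#' @param seed Base seed.
#' @return A named list of `"synthetic_truth"` objects (a single object if
#'   one name was requested).
#' @export
standard_fixtures <- function(names = c("stationary-50Hz", "drifting-peak",
                                        "switching-topography", "two-frequency",
                                        "meg-strong", "clean-only"),
                              seed = 1000) {
  names <- match.arg(names, several.ok = TRUE)
  build <- function(name) {
    nch <- if (name == "meg-strong") 64L else 24L
    bg <- pink_background(nch, 300, 250, seed = seed + match(name, c(
      "stationary-50Hz", "drifting-peak", "switching-topography",
      "two-frequency", "meg-strong", "clean-only")))
    topo <- function(k, n = nch) {
      w <- sin(seq_len(n) * k) + 0.3  # smooth, non-degenerate channel profile
      w / sqrt(sum(w^2))
    }
    if (name == "clean-only") {
      return(add_noise_sources(bg, list(), seed = seed))
    }
    if (name == "stationary-50Hz") {
      mk <- function(a) add_noise_sources(
        bg, noise_source_spec(50, a, topo(1)), seed = seed)
      a <- calibrate_amplitude(bg, mk, 50, target_ratio = 6)
      return(mk(a))
    }
    if (name == "drifting-peak") {
      mk <- function(a) add_noise_sources(
        bg, noise_source_spec(c(49.95, 50.05), a, topo(1)), seed = seed)
      a <- calibrate_amplitude(bg, mk, 50, target_ratio = 6)
      return(mk(a))
    }
    if (name == "switching-topography") {
      # nonstationary source: strong enough (mid EEG/MEG regime) that the
      # topography switches dominate the +/- 3 Hz covariance
      topos <- cbind(topo(1), topo(2), topo(3))
      mk <- function(a) add_noise_sources(
        bg, noise_source_spec(50, a, topos,
                              topo_change_points = c(100, 200)), seed = seed)
      a <- calibrate_amplitude(bg, mk, 50, target_ratio = 30)
      return(mk(a))
    }
    if (name == "two-frequency") {
      mk50 <- function(a) add_noise_sources(
        bg, noise_source_spec(50, a, topo(1)), seed = seed)
      a50 <- calibrate_amplitude(bg, mk50, 50, target_ratio = 6)
      mk21 <- function(a) add_noise_sources(
        bg, noise_source_spec(21, a, topo(2), active_interval = c(150, 300)),
        seed = seed)
      a21 <- calibrate_amplitude(bg, mk21, 21, target_ratio = 30)
      return(add_noise_sources(
        bg,
        list(noise_source_spec(50, a50, topo(1)),
             noise_source_spec(21, a21, topo(2), active_interval = c(150, 300))),
        seed = seed))
    }
    if (name == "meg-strong") {
      mk <- function(a) add_noise_sources(
        bg, noise_source_spec(50, a, topo(1)), seed = seed)
      a <- calibrate_amplitude(bg, mk, 50, target_ratio = 500)
      return(mk(a))
    }
    stop("unknown fixture ", name)
  }
  out <- lapply(names, build)
  names(out) <- names
  if (length(out) == 1) out[[1]] else out
}
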