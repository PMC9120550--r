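# Orchestration of the full adaptive cleaning: per-frequency chunked
# Zapline passes, evaluation of the cleaned spectrum, threshold adaptation
# and re-runs, and iteration over successive noise frequencies.

MAX_ADAPTATION_PASSES <- 10L
MAX_NOISE_FREQUENCIES <- 20L

new_loop_state <- function(f_target, cfg) {
  list(f_target = f_target,
       sigma = cfg$noise_comp_detect_sigma,
       fixed_nremove = cfg$fixed_nremove,
       initial_fixed = cfg$fixed_nremove,
       was_too_strong = FALSE,
       iteration = 0L)
}

#' One cleaning pass over all chunks at a noise frequency
#'
#' For each chunk of the plan: estimate the chunk spectrum (a single
#' full-chunk Welch segment, the finest resolution available), detect the
#' chunk's own peak frequency and whether the noise is present, decompose
#' the noise-band residual, choose the number of components to remove
#' (adaptive outlier count when the noise is present, the fixed minimum
#' otherwise) and clean. Chunks are re-concatenated in order.
#'
#' @param rec A [recording()].
#' @param f_target Target noise frequency (Hz).
#' @param plan A [find_chunk_boundaries()] plan tiling `rec`.
#' @param state Internal adaptation state (sigma, fixed_nremove); when
#'   `NULL`, fresh state from `cfg`.
#' @param cfg A [zap_config()].
#' @return List: `clean` (`recording`) and `chunks`, a per-chunk list of
#'   records (`n_removed`, `scores`, `f_peak`, `noise_present`).
#' @export
clean_frequency_pass <- function(rec, f_target, plan, state = NULL,
                                 cfg = zap_config()) {
  stopifnot(inherits(rec, "recording"), inherits(plan, "chunk_plan"))
  if (is.null(state)) state <- new_loop_state(f_target, cfg)
  nb <- length(plan$boundaries)
  if (plan$boundaries[1] != 0 || plan$boundaries[nb] != n_samples(rec)) {
    zap_abort("zap_invalid_argument", "chunk plan does not tile the recording")
  }
  out <- rec$data
  chunks <- vector("list", nb - 1L)
  for (ci in seq_len(nb - 1L)) {
    idx <- (plan$boundaries[ci] + 1L):plan$boundaries[ci + 1L]
    chunk <- recording(rec$data[, idx, drop = FALSE], rec$srate,
                       rec$channel_labels)
    if (cfg$search_individual_noise) {
      cspec <- welch_log_spectrum(chunk, n_samples(chunk))
      pk <- detect_chunk_peak(cspec, f_target, cfg)
      f_chunk <- pk$f_peak
      present <- pk$present
    } else {
      f_chunk <- f_target
      present <- TRUE
    }
    # absent noise: clean at the full-data peak with the fixed number only
    f_use <- if (present) f_chunk else f_target
    parts <- smooth_split(chunk, f_use)
    cov2 <- bias_covariances(parts$residual, f_use)
    dss <- dss_decompose(cov2$C0, cov2$C1, nkeep = cfg$nkeep)
    n_out <- if (present && cfg$adaptive_nremove) {
      iterative_outlier_count(dss$scores, state$sigma)
    } else 0L
    n_rm <- resolve_nremove(n_out, state$fixed_nremove, dss$n_effective,
                            noise_present = present,
                            adaptive = cfg$adaptive_nremove)
    cleaned_resid <- remove_components(parts$residual, dss, n_rm)
    out[, idx] <- parts$smoothed$data + cleaned_resid$data
    chunks[[ci]] <- list(n_removed = n_rm,
                         scores = dss$scores,
                         f_peak = f_chunk,
                         noise_present = present)
  }
  list(clean = recording(out, rec$srate, rec$channel_labels), chunks = chunks)
}

#' Judge a cleaned spectrum as too weak, too strong, or acceptable
#'
#' Computes the fine threshold on the cleaned spectrum around `f_target`.
#' Cleaning is too weak when more than `max_proportion_above_upper` of the
#' bins within `detailed_freq_bounds_upper` (a residual peak) lie above the
#' upper threshold; too strong when more than `max_proportion_below_lower`
#' of the bins within `detailed_freq_bounds_lower` (an introduced notch,
#' typically just below the noise frequency) lie below the lower threshold.
#'
#' @param clean_spec `spectrum_estimate` of the cleaned recording.
#' @param f_target Noise frequency (Hz).
#' @param cfg A [zap_config()].
#' @return List of class `"cleaning_verdict"`: `too_weak`, `too_strong`,
#'   `proportion_above`, `proportion_below`, `threshold`.
#' @export
evaluate_cleaning <- function(clean_spec, f_target, cfg = zap_config()) {
  thr <- fine_threshold(clean_spec, f_target, cfg)
  band_bins <- function(bounds) {
    band <- f_target + bounds
    if (band[1] < clean_spec$freqs[1] - 1e-9 ||
        band[2] > clean_spec$freqs[length(clean_spec$freqs)] + 1e-9) {
      zap_abort("zap_band_out_of_range",
                "evaluation band [%g, %g] Hz outside spectrum range",
                band[1], band[2])
    }
    idx <- which(clean_spec$freqs >= band[1] - 1e-9 &
                   clean_spec$freqs <= band[2] + 1e-9)
    if (length(idx) == 0) {
      zap_abort("zap_band_out_of_range",
                "no spectrum bins in evaluation band [%g, %g] Hz (resolution %g Hz)",
                band[1], band[2], clean_spec$freqs[2] - clean_spec$freqs[1])
    }
    idx
  }
  up <- band_bins(cfg$detailed_freq_bounds_upper)
  lo <- band_bins(cfg$detailed_freq_bounds_lower)
  curve <- clean_spec$mean_log_psd
  p_above <- mean(curve[up] > thr$upper)
  p_below <- mean(curve[lo] < thr$lower)
  structure(list(too_weak = p_above > cfg$max_proportion_above_upper,
                 too_strong = p_below > cfg$max_proportion_below_lower,
                 proportion_above = p_above,
                 proportion_below = p_below,
                 threshold = thr),
            class = "cleaning_verdict")
}

#' Adapt detection parameters after a verdict
#'
#' Too-strong cleaning takes precedence: sigma is raised by 0.25 (up to
#' `max_sigma`) and the fixed removal lowered by 1 (not below its initial
#' value), and a sticky flag is set so the cleaning can never become
#' stronger again. Too-weak cleaning (unless that flag is set) lowers
#' sigma by 0.25 (down to `min_sigma`) and raises the fixed removal by 1.
#' The pass is repeated only if some parameter actually changed and the
#' iteration cap has not been reached.
#'
#' @param verdict A [evaluate_cleaning()] verdict.
#' @param state Current loop state.
#' @param cfg A [zap_config()].
#' @return List: `state` (updated), `continue` (logical).
#' @export
adapt_parameters <- function(verdict, state, cfg = zap_config()) {
  state$iteration <- state$iteration + 1L
  changed <- FALSE
  if (!cfg$adaptive_sigma) {
    return(list(state = state, continue = FALSE))
  }
  if (verdict$too_strong) {
    state$was_too_strong <- TRUE
    new_sigma <- min(state$sigma + 0.25, cfg$max_sigma)
    new_fixed <- max(state$fixed_nremove - 1L, state$initial_fixed)
    changed <- (new_sigma != state$sigma) || (new_fixed != state$fixed_nremove)
    state$sigma <- new_sigma
    state$fixed_nremove <- new_fixed
  } else if (verdict$too_weak) {
    if (state$was_too_strong) {
      return(list(state = state, continue = FALSE))
    }
    new_sigma <- max(state$sigma - 0.25, cfg$min_sigma)
    new_fixed <- state$fixed_nremove + 1L
    changed <- (new_sigma != state$sigma) || (new_fixed != state$fixed_nremove)
    state$sigma <- new_sigma
    state$fixed_nremove <- new_fixed
  }
  list(state = state,
       continue = changed && state$iteration < MAX_ADAPTATION_PASSES)
}

#' Noise-to-surroundings power ratio at a frequency
#'
#' Ratio of the mean power in the band `f + detailed_freq_bounds_upper`
#' (default +/- 0.05 Hz) to the center power of the surrounding detection
#' window, both taken from the geometric-mean log spectrum. A ratio of 1
#' means no residual peak.
#'
#' @param spec A `spectrum_estimate`.
#' @param f Frequency (Hz).
#' @param cfg A [zap_config()].
#' @return Linear power ratio.
#' @export
noise_surroundings_ratio <- function(spec, f, cfg = zap_config()) {
  band <- f + cfg$detailed_freq_bounds_upper
  idx <- which(spec$freqs >= band[1] - 1e-9 & spec$freqs <= band[2] + 1e-9)
  if (length(idx) == 0) {
    zap_abort("zap_band_out_of_range", "no bins in band around %g Hz", f)
  }
  db_to_power_ratio(mean(spec$mean_log_psd[idx]) - center_power(spec, f, cfg))
}

#' Per-frequency cleaning analytics
#'
#' Removed-power proportions (over the whole spectrum, the noise band and
#' the 10 Hz region below the noise frequency) computed on the log
#' spectra, and the noise-to-surroundings ratios before and after
#' cleaning.
#'
#' @param raw_spec,clean_spec `spectrum_estimate`s before/after cleaning.
#' @param f Noise frequency (Hz).
#' @param cfg A [zap_config()].
#' @return Named list of analytics values.
#' @export
compute_analytics <- function(raw_spec, clean_spec, f, cfg = zap_config()) {
  stopifnot(length(raw_spec$freqs) == length(clean_spec$freqs))
  removed_prop <- function(idx) {
    if (length(idx) == 0) {
      zap_abort("zap_band_out_of_range", "empty analytics band at %g Hz", f)
    }
    1 - db_to_power_ratio(mean(clean_spec$mean_log_psd[idx]) -
                            mean(raw_spec$mean_log_psd[idx]))
  }
  freqs <- raw_spec$freqs
  band_u <- f + cfg$detailed_freq_bounds_upper
  below <- c(f - 11, f - 1)
  list(proportion_removed_power_full = removed_prop(seq_along(freqs)),
       proportion_removed_power_noise_band =
         removed_prop(which(freqs >= band_u[1] - 1e-9 & freqs <= band_u[2] + 1e-9)),
       proportion_removed_power_below_noise =
         removed_prop(which(freqs >= below[1] - 1e-9 & freqs <= below[2] + 1e-9)),
       ratio_noise_to_surroundings_raw = noise_surroundings_ratio(raw_spec, f, cfg),
       ratio_noise_to_surroundings_clean = noise_surroundings_ratio(clean_spec, f, cfg))
}

#' Fully automatic adaptive removal of frequency-specific noise
#'
#' The main entry point. Detects outlier frequencies in the geometric-mean
#' Welch spectrum (or takes `cfg$noisefreqs` verbatim), segments the
#' recording into chunks of spatially stable noise topography, cleans each
#' chunk with the Zapline operation at the chunk's own peak frequency,
#' evaluates the cleaned spectrum, and adapts the detection thresholds and
#' re-runs until the cleaning is neither too weak nor too strong. After a
#' frequency converges, the search continues from 0.05 Hz above it on the
#' cleaned data.
#'
#' @param rec A [recording()].
#' @param cfg A [zap_config()].
#' @param verbose Print one line per adaptation pass.
#' @return List of class `"zap_result"`: `clean` (the cleaned `recording`)
#'   and `report` (class `"zap_report"`) holding the final configuration
#'   (with the detected `noisefreqs` filled in, so re-running it on the
#'   same raw data replicates the output exactly), raw/clean spectra and
#'   per-frequency, per-chunk analytics.
#' @examples
#' \donttest{
#' fx <- standard_fixtures("stationary-50Hz")
#' res <- zap_clean(fx$combined)
#' res$report$frequencies[[1]]$analytics$ratio_noise_to_surroundings_clean
#' }
#' @export
zap_clean <- function(rec, cfg = zap_config(), verbose = FALSE) {
  stopifnot(inherits(rec, "recording"))
  cfg <- validate_config(cfg, rec)
  win <- cfg$win_size_complete_spectrum
  raw_spec <- welch_log_spectrum(rec, win)
  say <- function(...) if (verbose) message(sprintf(...))

  auto <- length(cfg$noisefreqs) == 0
  queue <- if (auto) NULL else as.list(cfg$noisefreqs)
  search_min <- cfg$minfreq
  current <- rec
  current_spec <- raw_spec
  freq_records <- list()

  repeat {
    if (length(freq_records) >= MAX_NOISE_FREQUENCIES) break
    if (auto) {
      f <- detect_next_noise_frequency(current_spec, search_min, cfg$maxfreq, cfg)
      if (is.null(f)) break
    } else {
      if (length(queue) == 0) break
      f <- queue[[1]]
      queue <- queue[-1]
    }
    say("noise frequency %g Hz: segmenting", f)
    plan <- segment_recording(current, f, cfg)
    state <- new_loop_state(f, cfg)
    input_spec <- current_spec
    pass <- NULL
    clean_spec <- NULL
    verdict <- NULL
    repeat {
      pass <- clean_frequency_pass(current, f, plan, state, cfg)
      clean_spec <- welch_log_spectrum(pass$clean, win)
      verdict <- evaluate_cleaning(clean_spec, f, cfg)
      say("  pass %d @ %g Hz: sigma=%.2f fixed=%d above=%.4f below=%.4f %s",
          state$iteration + 1L, f, state$sigma, state$fixed_nremove,
          verdict$proportion_above, verdict$proportion_below,
          if (verdict$too_strong) "too strong"
          else if (verdict$too_weak) "too weak" else "ok")
      ad <- adapt_parameters(verdict, state, cfg)
      state <- ad$state
      if (!ad$continue) break
    }
    removed <- recording(current$data - pass$clean$data, rec$srate,
                         rec$channel_labels)
    removed_curve <- tryCatch(
      welch_log_spectrum(removed, win)$mean_log_psd,
      error = function(e) rep(NA_real_, length(clean_spec$freqs)))
    scores_list <- lapply(pass$chunks, `[[`, "scores")
    ncomp_max <- max(vapply(scores_list, length, integer(1)))
    score_mat <- vapply(scores_list, function(s) {
      c(s, rep(NA_real_, ncomp_max - length(s)))
    }, numeric(ncomp_max))
    score_mat <- matrix(score_mat, nrow = ncomp_max)
    freq_records[[length(freq_records) + 1L]] <- list(
      frequency = f,
      sigma_used = state$sigma,
      fixed_nremove_used = state$fixed_nremove,
      n_passes = state$iteration,
      was_too_strong = state$was_too_strong,
      proportion_above_upper = verdict$proportion_above,
      proportion_below_lower = verdict$proportion_below,
      analytics = compute_analytics(input_spec, clean_spec, f, cfg),
      n_removed = vapply(pass$chunks, `[[`, integer(1) + 0, "n_removed"),
      artifact_scores = score_mat,
      chunk_peak_frequency = vapply(pass$chunks, `[[`, numeric(1), "f_peak"),
      noise_present_flag = vapply(pass$chunks, `[[`, logical(1), "noise_present"),
      chunk_boundaries = plan$boundaries,
      chunk_method = plan$method,
      input_mean_log_psd = input_spec$mean_log_psd,
      clean_mean_log_psd = clean_spec$mean_log_psd,
      removed_mean_log_psd = removed_curve,
      fine_threshold_clean = verdict$threshold,
      detection_center_power = center_power(input_spec, f, cfg))
    current <- pass$clean
    current_spec <- clean_spec
    if (auto) search_min <- f + 0.05
  }

  final_cfg <- cfg
  final_cfg$noisefreqs <- vapply(freq_records, `[[`, numeric(1), "frequency")
  report <- structure(list(final_config = final_cfg,
                           raw_log_spectrum = raw_spec,
                           clean_log_spectrum = current_spec,
                           frequencies = freq_records),
                      class = "zap_report")
  structure(list(clean = current, report = report), class = "zap_result")
}

#' @export
print.zap_report <- function(x, ...) {
  cat(sprintf("<zap_report> %d noise frequenc%s cleaned\n",
              length(x$frequencies),
              if (length(x$frequencies) == 1) "y" else "ies"))
  for (fr in x$frequencies) {
    cat(sprintf("  %7.3f Hz: ratio %5.2f -> %5.2f, sigma %.2f, %d chunk(s), %d pass(es)\n",
                fr$frequency,
                fr$analytics$ratio_noise_to_surroundings_raw,
                fr$analytics$ratio_noise_to_surroundings_clean,
                fr$sigma_used, length(fr$n_removed), fr$n_passes))
  }
  invisible(x)
}

#' @export
print.zap_result <- function(x, ...) {
  print(x$clean)
  print(x$report)
  invisible(x)
}
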