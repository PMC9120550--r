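# Per-frequency diagnostic figure: eight panels summarizing detection,
# per-chunk cleaning, component scores, and the resulting spectra. Colors
# follow the Okabe-Ito colorblind-friendly palette.

#' @importFrom rlang .data
NULL

PAL <- c(raw = "#0072B2", clean = "#009E73", removed = "#D55E00",
         threshold = "#CC79A7")

#' Build the eight diagnostic panels for one cleaned frequency
#'
#' Panels: (a) zoomed raw spectrum (+/- 1.1 Hz) with the detection
#' threshold; (b) removed components per chunk (noise-absent chunks
#' marked); (c) chunk peak frequencies; (d) mean artifact scores with the
#' mean-removal line, abscissa cut to one-third of the components; (e)
#' zoomed cleaned spectrum with the fine thresholds, y-axis shared with
#' (a); (f) full raw spectrum with the search range shaded; (g) clean and
#' removed spectra on an axis relative to the noise frequency (1 = the
#' noise frequency); (h) raw vs clean over the 10 Hz below the noise
#' frequency with the analytics in the title.
#'
#' @param report A `zap_report`.
#' @param index Index into `report$frequencies`.
#' @return A list of class `"frequency_figure"`: `panels` (named list of 8
#'   ggplot objects, `a` ... `h`) and `assembled` (a patchwork).
#' @export
build_frequency_figure <- function(report, index = 1) {
  stopifnot(inherits(report, "zap_report"))
  fr <- report$frequencies[[index]]
  cfg <- report$final_config
  f <- fr$frequency
  freqs <- report$raw_log_spectrum$freqs
  zoom <- freqs >= f - 1.1 & freqs <= f + 1.1
  dz <- data.frame(freq = freqs[zoom],
                   raw = fr$input_mean_log_psd[zoom],
                   clean = fr$clean_mean_log_psd[zoom])
  det_thr <- fr$detection_center_power + cfg$coarse_freq_detect_power_diff
  ylim_a <- range(c(dz$raw, dz$clean, det_thr))

  p_a <- ggplot2::ggplot(dz, ggplot2::aes(.data$freq, .data$raw)) +
    ggplot2::geom_line(color = PAL["raw"]) +
    ggplot2::geom_hline(yintercept = det_thr, color = PAL["threshold"]) +
    ggplot2::coord_cartesian(ylim = ylim_a) +
    ggplot2::labs(title = sprintf("(a) raw spectrum %.2f Hz", f),
                  x = "frequency (Hz)", y = "power (10*log10 PSD)")

  nchunk <- length(fr$n_removed)
  db <- data.frame(chunk = seq_len(nchunk), n = fr$n_removed,
                   present = fr$noise_present_flag)
  p_b <- ggplot2::ggplot(db, ggplot2::aes(.data$chunk, .data$n,
                                          fill = .data$present)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = unname(PAL["raw"]),
                                          `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(title = sprintf("(b) removed/chunk (mean %.1f)",
                                  mean(fr$n_removed)),
                  x = "chunk", y = "# removed")

  dc <- data.frame(chunk = seq_len(nchunk), f = fr$chunk_peak_frequency)
  p_c <- ggplot2::ggplot(dc, ggplot2::aes(.data$chunk, .data$f)) +
    ggplot2::geom_point(color = PAL["raw"]) +
    ggplot2::geom_hline(yintercept = f, linetype = 2, color = "grey50") +
    ggplot2::labs(title = "(c) chunk peak frequency", x = "chunk", y = "Hz")

  mean_scores <- rowMeans(fr$artifact_scores, na.rm = TRUE)
  ncomp <- length(mean_scores)
  cut <- max(2L, ceiling(ncomp / 3))
  dd <- data.frame(comp = seq_len(ncomp), score = mean_scores)
  p_d <- ggplot2::ggplot(dd[dd$comp <= cut, ],
                         ggplot2::aes(.data$comp, .data$score)) +
    ggplot2::geom_line(color = PAL["raw"]) +
    ggplot2::geom_point(color = PAL["raw"]) +
    ggplot2::geom_vline(xintercept = mean(fr$n_removed),
                        color = PAL["removed"]) +
    ggplot2::coord_cartesian(xlim = c(1, cut)) +
    ggplot2::labs(title = sprintf("(d) mean scores (sigma %.2f)", fr$sigma_used),
                  x = "component", y = "score")

  thr <- fr$fine_threshold_clean
  p_e <- ggplot2::ggplot(dz, ggplot2::aes(.data$freq, .data$clean)) +
    ggplot2::geom_line(color = PAL["clean"]) +
    ggplot2::geom_hline(yintercept = thr$upper, color = PAL["threshold"]) +
    ggplot2::geom_hline(yintercept = thr$lower, color = PAL["threshold"],
                        linetype = 2) +
    ggplot2::coord_cartesian(ylim = ylim_a) +
    ggplot2::labs(title = sprintf("(e) clean spectrum (above %.3f below %.3f)",
                                  fr$proportion_above_upper,
                                  fr$proportion_below_lower),
                  x = "frequency (Hz)", y = "power (10*log10 PSD)")

  df_full <- data.frame(freq = freqs, raw = fr$input_mean_log_psd)
  p_f <- ggplot2::ggplot(df_full[df_full$freq > 0, ],
                         ggplot2::aes(.data$freq, .data$raw)) +
    ggplot2::annotate("rect", xmin = cfg$minfreq, xmax = cfg$maxfreq,
                      ymin = -Inf, ymax = Inf, alpha = 0.12,
                      fill = PAL["threshold"]) +
    ggplot2::geom_line(color = PAL["raw"]) +
    ggplot2::labs(title = "(f) full raw spectrum (search range shaded)",
                  x = "frequency (Hz)", y = "power (10*log10 PSD)")

  rel <- freqs / f
  keep_g <- rel > 0 & rel <= min(3, max(rel))
  dg <- data.frame(rel = rep(rel[keep_g], 2),
                   power = c(fr$clean_mean_log_psd[keep_g],
                             fr$removed_mean_log_psd[keep_g]),
                   what = rep(c("clean", "removed"), each = sum(keep_g)))
  p_g <- ggplot2::ggplot(dg, ggplot2::aes(.data$rel, .data$power,
                                          color = .data$what)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_color_manual(values = c(clean = unname(PAL["clean"]),
                                           removed = unname(PAL["removed"]))) +
    ggplot2::labs(title = "(g) clean vs removed (1 = noise freq)",
                  x = "frequency / noise frequency", y = "power")

  below <- freqs >= f - 11 & freqs <= f - 1
  dh <- data.frame(freq = rep(freqs[below], 2),
                   power = c(fr$input_mean_log_psd[below],
                             fr$clean_mean_log_psd[below]),
                   what = rep(c("raw", "clean"), each = sum(below)))
  an <- fr$analytics
  p_h <- ggplot2::ggplot(dh, ggplot2::aes(.data$freq, .data$power,
                                          color = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(raw = unname(PAL["raw"]),
                                           clean = unname(PAL["clean"]))) +
    ggplot2::labs(title = sprintf(
      "(h) removed: full %.3f, band %.3f, below %.3f; ratio %.2f -> %.2f",
      an$proportion_removed_power_full,
      an$proportion_removed_power_noise_band,
      an$proportion_removed_power_below_noise,
      an$ratio_noise_to_surroundings_raw,
      an$ratio_noise_to_surroundings_clean),
      x = "frequency (Hz)", y = "power")

  panels <- list(a = p_a, b = p_b, c = p_c, d = p_d,
                 e = p_e, f = p_f, g = p_g, h = p_h)
  assembled <- patchwork::wrap_plots(panels, nrow = 2)
  structure(list(panels = panels, assembled = assembled, frequency = f),
            class = "frequency_figure")
}

#' Render the diagnostic figure for one frequency to disk
#'
#' Writes a single PNG (or PDF, by extension) per noise frequency;
#' re-rendering for the same path overwrites the previous version, so
#' after adaptation only the final state remains.
#'
#' @param report A `zap_report`.
#' @param index Index into `report$frequencies`.
#' @param outpath Output file (`.png` or `.pdf`).
#' @param width,height,dpi Device geometry passed to [ggplot2::ggsave()].
#' @return `outpath`, invisibly.
#' @export
render_frequency_figure <- function(report, index, outpath,
                                    width = 16, height = 7, dpi = 110) {
  fig <- build_frequency_figure(report, index)
  ok <- tryCatch({
    ggplot2::ggsave(outpath, fig$assembled, width = width, height = height,
                    dpi = dpi)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    zap_abort("zap_render_failed", "could not render %s: %s", outpath,
              conditionMessage(ok))
  }
  invisible(outpath)
}
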