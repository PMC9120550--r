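#' Zero-phase narrowband filter around a noise frequency
#'
#' Band-passes every channel to `f +/- halfwidth` Hz with a forward-
#' backward (zero-phase) order-2 Butterworth filter, isolating the noise
#' band whose spatial covariance the segmentation tracks.
#'
#' @param rec A [recording()].
#' @param f Center frequency (Hz).
#' @param halfwidth Half bandwidth in Hz (default 3).
#' @return A filtered `recording` of the same shape.
#' @export
narrowband_filter <- function(rec, f, halfwidth = 3) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$srate / 2
  if (f - halfwidth <= 0 || f + halfwidth >= nyq) {
    zap_abort("zap_band_out_of_range",
              "band [%g, %g] Hz must lie strictly inside (0, %g) Hz",
              f - halfwidth, f + halfwidth, nyq)
  }
  bf <- signal::butter(2, c(f - halfwidth, f + halfwidth) / nyq, type = "pass")
  out <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  recording(out, rec$srate, rec$channel_labels)
}

#' Covariance-stationarity distance series
#'
#' Splits the (narrowband) recording into non-overlapping 1 s epochs,
#' computes the channel x channel covariance matrix of each, scales every
#' matrix by its own Frobenius norm (so the measure is invariant to overall
#' amplitude), and returns the Frobenius distance between successive
#' matrices. Large values mark changes of the noise topography.
#'
#' @param nb A (typically narrowband-filtered) `recording`.
#' @return Numeric vector of length `n_epochs - 1`; element `i` is the
#'   distance between epochs `i` and `i + 1`. The epoch length in samples
#'   is attached as attribute `"epoch_samples"`.
#' @export
covariance_distance_series <- function(nb) {
  stopifnot(inherits(nb, "recording"))
  ep <- as.integer(floor(nb$srate))
  ne <- n_samples(nb) %/% ep
  if (ne < 2) {
    zap_abort("zap_too_few_epochs",
              "need at least 2 full 1 s epochs, recording has %d", ne)
  }
  covs <- vector("list", ne)
  for (i in seq_len(ne)) {
    seg <- nb$data[, ((i - 1L) * ep + 1L):(i * ep), drop = FALSE]
    C <- stats::cov(t(seg))
    nf <- sqrt(sum(C^2))
    covs[[i]] <- if (nf > 0) C / nf else C
  }
  d <- vapply(seq_len(ne - 1L), function(i) {
    sqrt(sum((covs[[i + 1L]] - covs[[i]])^2))
  }, numeric(1))
  attr(d, "epoch_samples") <- ep
  d
}

#' Chunk boundaries from the covariance distance series
#'
#' The distance series is first detrended by a running median (window of
#' twice the minimum chunk length), so a change in the overall noise
#' regime (e.g. a source switching on) does not inflate the detection
#' threshold; peaks of the detrended series (local maxima above
#' `median + 3 x IQR`) become chunk boundaries at the corresponding epoch
#' edge. Candidate boundaries are accepted in time order; any boundary
#' closer than `min_chunk_length` seconds to the previously accepted
#' boundary or to either end of the recording is skipped. With
#' `cfg$chunk_length > 0` fixed-length chunks are returned instead, and if
#' no peak survives a single chunk spanning the recording results. A final
#' remainder shorter than `min_chunk_length` is merged into its
#' predecessor, so no short chunk is ever emitted.
#'
#' @param dist Distance series from [covariance_distance_series()].
#' @param srate Sampling rate (Hz).
#' @param n_samples_total Total number of samples in the recording.
#' @param cfg A [zap_config()].
#' @return An object of class `"chunk_plan"`: `boundaries` (0-based sample
#'   indices, first 0, last `n_samples_total`, half-open chunks) and
#'   `method` (`"adaptive"`, `"fixed"` or `"single"`).
#' @export
find_chunk_boundaries <- function(dist, srate, n_samples_total, cfg = zap_config()) {
  min_len <- cfg$min_chunk_length * srate
  mk_plan <- function(bounds, method) {
    bounds <- sort(unique(c(0, bounds, n_samples_total)))
    # merge a short final remainder into its predecessor
    nb <- length(bounds)
    if (nb >= 3 && (bounds[nb] - bounds[nb - 1]) < min_len) {
      bounds <- bounds[-(nb - 1)]
    }
    structure(list(boundaries = bounds, method = method), class = "chunk_plan")
  }
  if (cfg$chunk_length > 0) {
    step <- round(cfg$chunk_length * srate)
    inner <- seq(step, n_samples_total - 1, by = step)
    return(mk_plan(inner, if (length(inner)) "fixed" else "single"))
  }
  ep <- attr(dist, "epoch_samples")
  if (is.null(ep)) ep <- as.integer(floor(srate))
  n <- length(dist)
  # local baseline: running median over ~2x the minimum chunk length
  k <- min(2L * as.integer(cfg$min_chunk_length) + 1L, n)
  if (k %% 2L == 0L) k <- k - 1L
  detr <- if (k >= 3) dist - stats::runmed(dist, k, endrule = "median") else dist - stats::median(dist)
  thr <- stats::median(detr) + 3 * stats::IQR(detr)
  is_peak <- rep(FALSE, n)
  for (i in seq_len(n)) {
    left <- if (i > 1) detr[i - 1] else -Inf
    right <- if (i < n) detr[i + 1] else -Inf
    is_peak[i] <- detr[i] > thr && detr[i] >= left && detr[i] >= right
  }
  accepted <- numeric(0)
  prev <- 0
  for (i in which(is_peak)) {
    b <- i * ep   # boundary at the edge between epochs i and i+1
    if (b - prev >= min_len && n_samples_total - b >= min_len) {
      accepted <- c(accepted, b)
      prev <- b
    }
  }
  mk_plan(accepted, if (length(accepted)) "adaptive" else "single")
}

#' @export
print.chunk_plan <- function(x, ...) {
  cat(sprintf("<chunk_plan> %d chunk(s), method '%s'\n",
              length(x$boundaries) - 1L, x$method))
  invisible(x)
}

#' @rdname find_chunk_boundaries
#' @param plan A `chunk_plan`.
#' @export
n_chunks <- function(plan) length(plan$boundaries) - 1L

#' Segment a recording into chunks of stable noise topography
#'
#' Convenience wrapper: narrowband-filters around `f`, computes the
#' covariance distance series and derives the chunk plan.
#'
#' @inheritParams narrowband_filter
#' @param cfg A [zap_config()].
#' @export
segment_recording <- function(rec, f, cfg = zap_config()) {
  if (cfg$chunk_length > 0) {
    return(find_chunk_boundaries(numeric(0), rec$srate, n_samples(rec), cfg))
  }
  nb <- narrowband_filter(rec, f)
  d <- covariance_distance_series(nb)
  find_chunk_boundaries(d, rec$srate, n_samples(rec), cfg)
}
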