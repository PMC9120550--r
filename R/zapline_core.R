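#' Split a chunk into a spectrally smooth part and a noise-band residual
#'
#' Applies a moving-average smoother whose length equals the noise period
#' `srate / f`, which has spectral nulls at `f` and all its harmonics. The
#' residual (chunk minus smoothed) therefore contains the noise and little
#' else; summing the two parts restores the chunk exactly, which is what
#' preserves the rank of the final cleaned data. Fractional periods are
#' handled by linearly weighting the moving averages of the two flanking
#' integer lengths.
#'
#' @param chunk A [recording()].
#' @param f Noise frequency (Hz), below Nyquist.
#' @return List of two recordings, `smoothed` and `residual`, with
#'   `smoothed$data + residual$data == chunk$data`.
#' @export
smooth_split <- function(chunk, f) {
  stopifnot(inherits(chunk, "recording"))
  if (f >= chunk$srate / 2) {
    zap_abort("zap_frequency_too_high",
              "noise frequency %g Hz not below Nyquist (%g Hz)", f, chunk$srate / 2)
  }
  p <- chunk$srate / f
  n1 <- floor(p)
  w <- p - n1
  sm <- moving_average_rows(chunk$data, n1)
  if (w > 1e-12) {
    sm2 <- moving_average_rows(chunk$data, n1 + 1L)
    sm <- (1 - w) * sm + w * sm2
  }
  list(smoothed = recording(sm, chunk$srate, chunk$channel_labels),
       residual = recording(chunk$data - sm, chunk$srate, chunk$channel_labels))
}

#' Baseline and noise-biased covariance matrices
#'
#' `C0` is the covariance of the residual. `C1` is the covariance of the
#' residual reconstructed from only the DFT bins nearest the noise
#' frequency and its harmonics (`k * f` for `k = 1 ... floor(Nyquist/f)`),
#' averaged over consecutive length-`nfft` windows. `C1` is the biasing
#' matrix of the joint decorrelation: its leading generalized eigenvectors
#' are the spatial components with the highest noise-band power.
#'
#' @param residual A `recording` (the noise-band part from [smooth_split()]).
#' @param f Noise frequency (Hz).
#' @param nfft DFT window length in samples; default `2^round(log2(srate))`
#'   capped at the chunk length.
#' @return List with matrices `C0`, `C1` (channels x channels) and the
#'   `nfft` used.
#' @export
bias_covariances <- function(residual, f, nfft = NULL) {
  stopifnot(inherits(residual, "recording"))
  ns <- n_samples(residual)
  if (is.null(nfft)) nfft <- min(2^round(log2(residual$srate)), ns)
  nfft <- as.integer(nfft)
  if (ns < nfft) {
    zap_abort("zap_chunk_shorter_than_nfft",
              "residual length (%d) shorter than nfft (%d)", ns, nfft)
  }
  x <- residual$data - rowMeans(residual$data)
  C0 <- tcrossprod(x) / ns
  nyq <- residual$srate / 2
  harmonics <- f * seq_len(max(1L, floor(nyq / f)))
  harmonics <- harmonics[harmonics <= nyq + 1e-9]
  binfreqs <- (0:(nfft - 1L)) * residual$srate / nfft
  # nearest DFT bin per harmonic (index into the non-negative-frequency half)
  keep <- unique(vapply(harmonics, function(h) {
    which.min(abs(binfreqs[1:(nfft %/% 2L + 1L)] - h))
  }, integer(1)))
  nwin <- ns %/% nfft
  C1 <- matrix(0, nrow(x), nrow(x))
  total <- 0L
  for (wdx in seq_len(nwin)) {
    seg <- x[, ((wdx - 1L) * nfft + 1L):(wdx * nfft), drop = FALSE]
    ft <- stats::mvfft(t(seg))            # nfft x channels
    mask <- rep(FALSE, nfft)
    mask[keep] <- TRUE
    mirror <- nfft - keep + 2L            # conjugate bins (skip DC / Nyquist)
    mirror <- mirror[mirror >= 1L & mirror <= nfft]
    mask[mirror] <- TRUE
    ft[!mask, ] <- 0
    nb <- Re(stats::mvfft(ft, inverse = TRUE)) / nfft   # narrowband segment
    C1 <- C1 + crossprod(nb)
    total <- total + nfft
  }
  C1 <- C1 / total
  list(C0 = C0, C1 = C1, nfft = nfft)
}

#' Joint decorrelation (DSS) of the noise-band residual
#'
#' Whitens the baseline covariance `C0` (discarding dimensions with
#' eigenvalues below `1e-9` of the largest, and at most `nkeep` when
#' `nkeep > 0`), then eigendecomposes the whitened biased covariance `C1`.
#' Components are ordered by descending eigenvalue ("score"), the ratio of
#' noise-band power to total power each component captures.
#'
#' @param C0,C1 Covariance matrices from [bias_covariances()].
#' @param nkeep Optional PCA dimension cap (0 = none).
#' @return An object of class `"dss_decomposition"`: `rotation`
#'   (channels x components; component time courses are
#'   `t(rotation) %*% data`), `scores` (non-increasing, >= 0),
#'   `n_effective`.
#' @export
dss_decompose <- function(C0, C1, nkeep = 0) {
  stopifnot(is.matrix(C0), is.matrix(C1), nrow(C0) == nrow(C1))
  if (all(C0 == 0)) {
    zap_abort("zap_degenerate_covariance", "baseline covariance is all zero")
  }
  e0 <- eigen((C0 + t(C0)) / 2, symmetric = TRUE)
  keep <- which(e0$values > 1e-9 * e0$values[1])
  if (nkeep > 0) keep <- keep[seq_len(min(nkeep, length(keep)))]
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), length(keep))
  C1w <- crossprod(W, C1 %*% W)
  e1 <- eigen((C1w + t(C1w)) / 2, symmetric = TRUE)
  rotation <- W %*% e1$vectors
  scores <- pmax(e1$values, 0)
  structure(list(rotation = rotation,
                 scores = scores,
                 n_effective = length(keep)),
            class = "dss_decomposition")
}

#' @export
print.dss_decomposition <- function(x, ...) {
  cat(sprintf("<dss_decomposition> %d effective components; top scores: %s\n",
              x$n_effective,
              paste(signif(utils::head(x$scores, 3), 3), collapse = ", ")))
  invisible(x)
}

#' Project noise components out of the residual
#'
#' Removes the time courses of the first `n_remove` DSS components from
#' every channel of the residual by least squares.
#'
#' @param residual A `recording`.
#' @param dss A [dss_decompose()] result.
#' @param n_remove Number of leading components to remove
#'   (`0 <= n_remove <= n_effective`).
#' @return The cleaned residual `recording`.
#' @export
remove_components <- function(residual, dss, n_remove) {
  stopifnot(inherits(residual, "recording"), inherits(dss, "dss_decomposition"))
  if (n_remove < 0 || n_remove > dss$n_effective) {
    zap_abort("zap_nremove_out_of_range",
              "n_remove = %d outside [0, %d]", n_remove, dss$n_effective)
  }
  if (n_remove == 0) return(residual)
  tc <- crossprod(dss$rotation[, seq_len(n_remove), drop = FALSE],
                  residual$data)                     # n_remove x samples
  gram <- tcrossprod(tc)
  beta <- residual$data %*% t(tc) %*% solve(gram)
  recording(residual$data - beta %*% tc, residual$srate, residual$channel_labels)
}

#' Clean one chunk with the Zapline operation
#'
#' Splits the chunk around `f`, decomposes the noise-band residual by
#' joint decorrelation, removes the `n_remove` leading components and
#' recombines with the smooth part. With `n_remove = 0` the chunk is
#' returned unchanged (the split is exactly complementary).
#'
#' @param chunk A [recording()].
#' @param f Noise frequency (Hz).
#' @param n_remove Number of components to remove.
#' @param cfg A [zap_config()] (for `nkeep`).
#' @return List: `clean` (`recording`), `scores` (DSS scores), `dss`.
#' @export
zapline_chunk <- function(chunk, f, n_remove, cfg = zap_config()) {
  parts <- smooth_split(chunk, f)
  cov2 <- bias_covariances(parts$residual, f)
  dss <- dss_decompose(cov2$C0, cov2$C1, nkeep = cfg$nkeep)
  n_remove <- min(n_remove, dss$n_effective)
  cleaned_resid <- remove_components(parts$residual, dss, n_remove)
  clean <- recording(parts$smoothed$data + cleaned_resid$data,
                     chunk$srate, chunk$channel_labels)
  list(clean = clean, scores = dss$scores, dss = dss, n_removed = n_remove)
}
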