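#' Iterative outlier count on component scores
#'
#' Repeatedly removes scores strictly greater than
#' `mean + sigma * SD` of the scores still in play, recomputing mean and
#' SD each pass, until a pass removes nothing. The number removed is the
#' number of components that load abnormally strongly on the noise.
#' The SD is the sample standard deviation (n - 1 denominator).
#'
#' @param scores Numeric vector of DSS scores.
#' @param sigma SD multiplier.
#' @return Integer count of outliers.
#' @export
iterative_outlier_count <- function(scores, sigma) {
  if (length(scores) == 0) zap_abort("zap_empty_scores", "scores is empty")
  if (!all(is.finite(scores))) {
    zap_abort("zap_invalid_argument", "scores must be finite")
  }
  remaining <- scores
  removed <- 0L
  repeat {
    if (length(remaining) < 2) break
    thr <- mean(remaining) + sigma * stats::sd(remaining)
    out <- remaining > thr
    if (!any(out)) break
    removed <- removed + sum(out)
    remaining <- remaining[!out]
  }
  removed
}

#' Resolve the number of components to remove in a chunk
#'
#' When the chunk carries the noise and adaptive removal is on, the larger
#' of the detected outlier count and the configured fixed minimum is used;
#' otherwise the fixed number alone (so chunks without the artifact are
#' never cleaned aggressively). In all cases the result is capped at
#' one-fifth of the available components, to prevent removing an
#' unreasonable share of the data's spatial dimensions.
#'
#' @param n_outliers Outlier count from [iterative_outlier_count()].
#' @param fixed_nremove Configured fixed/minimum removal.
#' @param n_components Number of available components.
#' @param noise_present Was the noise peak detected in this chunk?
#' @param adaptive Is adaptive removal enabled?
#' @return Integer number of components to remove.
#' @export
resolve_nremove <- function(n_outliers, fixed_nremove, n_components,
                            noise_present = TRUE, adaptive = TRUE) {
  stopifnot(n_components >= 1)
  n <- if (noise_present && adaptive) max(n_outliers, fixed_nremove) else fixed_nremove
  n <- min(n, floor(n_components / 5))
  max(as.integer(n), 0L)
}
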