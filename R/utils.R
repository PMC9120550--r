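#' Run an expression under a fixed RNG state
#'
#' Seeds the generator locally and restores the caller's `.Random.seed`
#' afterwards, so deterministic generators do not disturb the global RNG
#' stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Centered moving average of each row of a channels x samples matrix.
# Even lengths use the symmetric kernel (1/2, 1, ..., 1, 1/2)/n so the
# output is not half-sample shifted; boxcar spectral nulls at k*srate/n
# are preserved. Edges are handled by reflection padding so the
# complement identity x = ma + (x - ma) holds over the full length.
moving_average_rows <- function(x, n) {
  stopifnot(n >= 1)
  if (n == 1) return(x)
  if (n %% 2 == 1) {
    kern <- rep(1 / n, n)
  } else {
    kern <- c(0.5, rep(1, n - 1), 0.5) / n
  }
  half <- (length(kern) - 1) / 2
  ns <- ncol(x)
  pad <- min(half, ns - 1)
  # reflection padding (without repeating the edge sample)
  left <- x[, pmin(pad + 1, ns):2, drop = FALSE]
  right <- x[, (ns - 1):max(ns - pad, 1), drop = FALSE]
  if (pad < half) {
    # degenerate: kernel longer than signal allows; extend by further mirror
    reps <- ceiling(half / pad)
    left <- do.call(cbind, rep(list(left), reps))[, 1:half, drop = FALSE]
    right <- do.call(cbind, rep(list(right), reps))[, 1:half, drop = FALSE]
  }
  xp <- cbind(left, x, right)
  out <- t(apply(xp, 1, function(row) {
    stats::filter(row, kern, sides = 2)
  }))
  out <- out[, (half + 1):(half + ns), drop = FALSE]
  storage.mode(out) <- "double"
  out
}

# nearest index in an ascending grid
nearest_bin <- function(grid, value) which.min(abs(grid - value))[1]
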