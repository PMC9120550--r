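# Shared in-code fixtures and independent oracles for the test suite.
# Everything is generated programmatically under fixed seeds.

# small multichannel recording: pink background + optional sinusoid
make_test_recording <- function(n_channels = 8, duration_s = 60, srate = 250,
                                f = NULL, amplitude = 0, topo = NULL,
                                seed = 42) {
  bg <- pink_background(n_channels, duration_s, srate, seed = seed)
  if (is.null(f) || amplitude == 0) return(bg)
  if (is.null(topo)) topo <- seq(0.5, 1.5, length.out = n_channels)
  tr <- add_noise_sources(bg, noise_source_spec(f, amplitude, topo),
                          seed = seed + 1)
  tr$combined
}

# a spectrum_estimate built directly from a curve, for threshold tests
fake_spectrum <- function(curve, df = 0.05, f0 = 0, srate = 250) {
  freqs <- f0 + (seq_along(curve) - 1) * df
  m <- rbind(curve, curve)
  structure(list(freqs = freqs, log_psd = m, mean_log_psd = curve,
                 srate = srate, window_samples = round(srate / df)),
            class = "spectrum_estimate")
}

# independent brute-force version of the iterative outlier rule, written
# directly from its verbal definition (explicit index bookkeeping,
# hand-computed mean and n-1 SD)
brute_force_outlier_count <- function(scores, sigma) {
  idx <- seq_along(scores)
  removed <- 0L
  repeat {
    s <- scores[idx]
    if (length(s) < 2) break
    m <- sum(s) / length(s)
    sdv <- sqrt(sum((s - m)^2) / (length(s) - 1))
    out <- which(s > m + sigma * sdv)
    if (length(out) == 0) break
    removed <- removed + length(out)
    idx <- idx[-out]
  }
  removed
}

# band power ratio helpers on a spectrum
band_mean_log <- function(spec, lo, hi) {
  mean(spec$mean_log_psd[spec$freqs >= lo - 1e-9 & spec$freqs <= hi + 1e-9])
}

# memoized fixture access: the catalog is deterministic, so cache builds
# across test blocks
.fixture_cache <- new.env(parent = emptyenv())
get_fixture <- function(name) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- standard_fixtures(name)
  }
  .fixture_cache[[name]]
}
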