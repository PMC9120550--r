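test_that("period-matched smoothing splits the data exactly and nulls the noise frequency", {
  srate <- 250
  const <- recording(matrix(5, 3, 2000), srate)
  parts <- smooth_split(const, 50)
  expect_equal(parts$smoothed$data, const$data, tolerance = 1e-12)
  expect_equal(max(abs(parts$residual$data)), 0, tolerance = 1e-10)

  t <- (0:(srate * 10 - 1)) / srate
  sine <- recording(rbind(sin(2 * pi * 50 * t), cos(2 * pi * 50 * t)), srate)
  ps <- smooth_split(sine, 50)           # integer period: srate/f = 5
  core <- (srate):(srate * 9)            # away from edges
  expect_lt(sqrt(mean(ps$smoothed$data[, core]^2)),
            1e-6 * sqrt(mean(sine$data^2)))
  expect_lt(max(abs(ps$smoothed$data + ps$residual$data - sine$data)),
            1e-12 * max(abs(sine$data)))

  # complement identity for arbitrary data and fractional period
  set.seed(4)
  arb <- recording(matrix(rnorm(3 * 5000), 3), srate)
  pa <- smooth_split(arb, 60)            # period 250/60 = 4.1667
  expect_lt(max(abs(pa$smoothed$data + pa$residual$data - arb$data)), 1e-12)

  expect_error(smooth_split(arb, 130), class = "zap_frequency_too_high")
})

test_that("biased covariance captures the harmonic bins", {
  srate <- 256
  set.seed(9)
  white <- recording(matrix(rnorm(4 * srate * 30), 4), srate)
  bc <- bias_covariances(white, 50, nfft = 256)
  nharm <- floor(128 / 50)               # 2 harmonics: 50, 100
  kept_bins <- 2 * nharm                 # conjugate pairs
  frac <- kept_bins / 256
  ratio <- sum(diag(bc$C1)) / sum(diag(bc$C0))
  expect_lt(abs(ratio / frac - 1), 0.2)

  t <- (0:(srate * 20 - 1)) / srate
  w <- c(1, 2, -1, 0.5)
  sine <- recording(w %o% sin(2 * pi * 50 * t) +
                      1e-4 * matrix(rnorm(4 * length(t)), 4), srate)
  bc2 <- bias_covariances(sine, 50, nfft = 256)
  ev <- eigen(bc2$C1, symmetric = TRUE)$vectors[, 1]
  cosang <- abs(sum(ev * w) / sqrt(sum(w^2)))
  expect_gt(cosang, 0.99)

  zero <- recording(matrix(0, 3, 2048), srate)
  bz <- bias_covariances(zero, 50, nfft = 256)
  expect_equal(max(abs(bz$C0)), 0)
  expect_equal(max(abs(bz$C1)), 0)
  expect_error(bias_covariances(recording(matrix(rnorm(6), 3), srate), 50,
                                nfft = 256),
               class = "zap_chunk_shorter_than_nfft")
})

test_that("joint decorrelation has the expected eigenstructure", {
  C0 <- diag(6)
  dss <- dss_decompose(C0, C0)
  expect_equal(dss$scores, rep(1, 6), tolerance = 1e-10)
  expect_true(all(diff(dss$scores) <= 1e-10))

  w <- c(3, 1, -2, 0.5, 0, 1)
  dss2 <- dss_decompose(diag(6), w %o% w)
  expect_equal(dss2$scores[1], sum(w^2), tolerance = 1e-8)
  expect_lt(max(abs(dss2$scores[-1])), 1e-8)

  set.seed(10)
  A <- matrix(rnorm(900), 30)
  C0big <- crossprod(A) / 30
  dss3 <- dss_decompose(C0big, C0big, nkeep = 5)
  expect_lte(dss3$n_effective, 5)

  expect_error(dss_decompose(matrix(0, 3, 3), diag(3)),
               class = "zap_degenerate_covariance")
})

test_that("component time courses are mutually uncorrelated", {
  rec <- make_test_recording(8, 40, 250, f = 50, amplitude = 3, seed = 21)
  parts <- smooth_split(rec, 50)
  bc <- bias_covariances(parts$residual, 50)
  dss <- dss_decompose(bc$C0, bc$C1)
  tc <- crossprod(dss$rotation, parts$residual$data - rowMeans(parts$residual$data))
  cc <- tcrossprod(tc) / ncol(tc)
  offdiag <- abs(cc[upper.tri(cc)])
  expect_lt(max(offdiag), 1e-6 * max(diag(cc)))
})

test_that("removing components attenuates planted rank-1 noise", {
  srate <- 250
  rec <- make_test_recording(8, 40, srate, f = 50, amplitude = 3, seed = 12)
  parts <- smooth_split(rec, 50)
  bc <- bias_covariances(parts$residual, 50)
  dss <- dss_decompose(bc$C0, bc$C1)

  expect_identical(remove_components(parts$residual, dss, 0)$data,
                   parts$residual$data)
  cleaned <- remove_components(parts$residual, dss, 1)
  spec_in <- welch_log_spectrum(parts$residual, srate * 8)
  spec_out <- welch_log_spectrum(cleaned, srate * 8)
  drop_db <- band_mean_log(spec_in, 49.9, 50.1) - band_mean_log(spec_out, 49.9, 50.1)
  expect_gt(drop_db, 20)
  expect_error(remove_components(parts$residual, dss, 99),
               class = "zap_nremove_out_of_range")
})

test_that("noise-band power is non-increasing in the number removed", {
  srate <- 250
  rec <- make_test_recording(8, 40, srate, f = 50, amplitude = 2, seed = 13)
  power_at_50 <- sapply(0:4, function(k) {
    z <- zapline_chunk(rec, 50, k)
    band_mean_log(welch_log_spectrum(z$clean, srate * 8), 49.9, 50.1)
  })
  expect_true(all(diff(power_at_50) <= 1e-9))
})

test_that("the zapline chunk operation preserves identity, conservation and rank", {
  srate <- 250
  rec <- make_test_recording(8, 40, srate, f = 50, amplitude = 2, seed = 14)
  z0 <- zapline_chunk(rec, 50, 0)
  expect_lt(max(abs(z0$clean$data - rec$data)), 1e-10 * max(abs(rec$data)))

  z1 <- zapline_chunk(rec, 50, 1)
  removed <- rec$data - z1$clean$data
  expect_lt(max(abs(z1$clean$data + removed - rec$data)), 1e-10)

  sv_in <- svd(rec$data, nu = 0, nv = 0)$d
  sv_out <- svd(z1$clean$data, nu = 0, nv = 0)$d
  expect_gt(sv_in[length(sv_in)], 1e-8 * sv_in[1])
  expect_gt(sv_out[length(sv_out)], 1e-8 * sv_out[1])

  spec_raw <- welch_log_spectrum(rec, srate * 8)
  spec_cln <- welch_log_spectrum(z1$clean, srate * 8)
  expect_gt(noise_surroundings_ratio(spec_raw, 50), 4)
  expect_lt(noise_surroundings_ratio(spec_cln, 50), 1.2)
})

test_that("zapline matches an analytic sinusoid-regression oracle on fixed topography", {
  # catalog-scale channel count: the removed spatial component carries a
  # 1/sqrt(n_channels) share of background, which bounds the agreement
  srate <- 250
  bg <- pink_background(24, 40, srate, seed = 15)
  topo <- seq(0.5, 1.5, length.out = 24)
  tr <- add_noise_sources(bg, noise_source_spec(50, 3, topo), seed = 16)
  chunk <- tr$combined

  # oracle: per-channel least-squares regression of sin/cos at 50 Hz
  t <- (0:(n_samples(chunk) - 1)) / srate
  X <- cbind(sin(2 * pi * 50 * t), cos(2 * pi * 50 * t))
  beta <- chunk$data %*% X %*% solve(crossprod(X))
  oracle_clean <- chunk$data - beta %*% t(X)

  z <- zapline_chunk(chunk, 50, 1)
  rel_rms <- sqrt(mean((z$clean$data - oracle_clean)^2)) /
    sqrt(mean(chunk$data^2))
  expect_lt(rel_rms, 0.05)
})
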