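test_that("cleaning evaluation flags residual peaks and introduced notches", {
  cfg <- zap_config()
  # 0 .. 100 Hz at 0.01 Hz resolution, flat
  flat <- fake_spectrum(rep(-3, 10001), df = 0.01)
  v <- evaluate_cleaning(flat, 50, cfg)
  expect_false(v$too_weak)
  expect_false(v$too_strong)

  # single hot bin inside +/- 0.05 Hz: 1/11 bins > 0.005 -> too weak
  peaky <- rep(-3, 10001)
  peaky[5001] <- 7
  vp <- evaluate_cleaning(fake_spectrum(peaky, df = 0.01), 50, cfg)
  expect_true(vp$too_weak)
  expect_false(vp$too_strong)
  expect_equal(vp$proportion_above, 1 / 11)

  # deep notch across the whole lower band -> too strong
  notch <- rep(-3, 10001)
  lower <- which((0:10000) * 0.01 >= 49.6 & (0:10000) * 0.01 <= 50.1)
  notch[lower] <- -13
  # keep some texture so the deviation is non-zero
  set.seed(40)
  notch <- notch + rnorm(10001, sd = 0.2)
  vn <- evaluate_cleaning(fake_spectrum(notch, df = 0.01), 50, cfg)
  expect_true(vn$too_strong)
  expect_error(evaluate_cleaning(flat, 0.2, cfg), class = "zap_error")
  coarse <- fake_spectrum(rep(-3, 101), df = 1)   # 1 Hz bins: band empty
  expect_error(evaluate_cleaning(coarse, 50.4, cfg),
               class = "zap_band_out_of_range")
})

test_that("parameter adaptation follows the strengthen/weaken rules with sticky too-strong", {
  cfg <- zap_config()
  st <- zaplinr:::new_loop_state(50, cfg)

  weak <- structure(list(too_weak = TRUE, too_strong = FALSE), class = "cleaning_verdict")
  strong <- structure(list(too_weak = FALSE, too_strong = TRUE), class = "cleaning_verdict")
  ok <- structure(list(too_weak = FALSE, too_strong = FALSE), class = "cleaning_verdict")

  a <- adapt_parameters(weak, st, cfg)
  expect_equal(a$state$sigma, 2.75)
  expect_equal(a$state$fixed_nremove, 2)
  expect_true(a$continue)

  st2 <- st; st2$sigma <- 2.5; st2$fixed_nremove <- 3; st2$was_too_strong <- TRUE
  a2 <- adapt_parameters(weak, st2, cfg)
  expect_equal(a2$state$sigma, 2.5)
  expect_equal(a2$state$fixed_nremove, 3)
  expect_false(a2$continue)

  st3 <- st; st3$sigma <- 4
  a3 <- adapt_parameters(strong, st3, cfg)
  expect_equal(a3$state$sigma, 4)       # already at the maximum
  expect_equal(a3$state$fixed_nremove, 1)
  expect_true(a3$state$was_too_strong)
  expect_false(a3$continue)             # nothing changed

  a4 <- adapt_parameters(ok, st, cfg)
  expect_false(a4$continue)

  # too-strong precedence: fixed_nremove never goes below its initial value
  st5 <- st; st5$fixed_nremove <- 1
  a5 <- adapt_parameters(strong, st5, cfg)
  expect_equal(a5$state$fixed_nremove, 1)
  expect_equal(a5$state$sigma, 3.25)
})

test_that("sigma stays within bounds over random adaptation trajectories", {
  cfg <- zap_config()
  set.seed(41)
  for (rep in 1:50) {
    st <- zaplinr:::new_loop_state(50, cfg)
    for (step in 1:12) {
      kind <- sample(3, 1)
      v <- structure(list(too_weak = kind == 1, too_strong = kind == 2),
                     class = "cleaning_verdict")
      st <- adapt_parameters(v, st, cfg)$state
      expect_gte(st$sigma, cfg$min_sigma)
      expect_lte(st$sigma, cfg$max_sigma)
      expect_gte(st$fixed_nremove, cfg$fixed_nremove)
    }
  }
})

test_that("analytics report removed-power proportions and band ratios", {
  cfg <- zap_config()
  curve <- rep(-2, 10001)
  raw <- fake_spectrum(curve, df = 0.01)
  same <- compute_analytics(raw, raw, 50, cfg)
  expect_equal(same$proportion_removed_power_full, 0)
  expect_equal(same$proportion_removed_power_noise_band, 0)
  expect_equal(same$ratio_noise_to_surroundings_raw, 1, tolerance = 1e-12)

  clean3db <- fake_spectrum(curve - 3, df = 0.01)
  a <- compute_analytics(raw, clean3db, 50, cfg)
  expect_equal(a$proportion_removed_power_full, 1 - 10^(-0.3), tolerance = 1e-9)
  expect_equal(a$proportion_removed_power_below_noise, 1 - 10^(-0.3),
               tolerance = 1e-9)
})

test_that("a noise-free pass removes exactly the fixed minimum per chunk", {
  rec <- pink_background(10, 70, 250, seed = 50)
  cfg <- validate_config(zap_config(), rec)
  plan <- find_chunk_boundaries(numeric(0), 250, n_samples(rec),
                                zap_config(chunk_length = 35))
  pass <- clean_frequency_pass(rec, 50, plan, NULL, cfg)
  expect_length(pass$chunks, 2)
  for (ch in pass$chunks) {
    expect_equal(ch$n_removed, 1)
  }
})

test_that("chunk peak frequencies track a drifting noise source", {
  bg <- pink_background(10, 300, 250, seed = 51)
  tr <- add_noise_sources(bg, noise_source_spec(c(49.95, 50.05), 4,
                                                seq(0.5, 1.5, length.out = 10)),
                          seed = 52)
  cfg <- validate_config(zap_config(chunk_length = 60), tr$combined)
  plan <- find_chunk_boundaries(numeric(0), 250, n_samples(tr$combined), cfg)
  pass <- clean_frequency_pass(tr$combined, 50, plan, NULL, cfg)
  peaks <- vapply(pass$chunks, `[[`, numeric(1), "f_peak")
  expect_length(peaks, 5)
  expect_true(all(vapply(pass$chunks, `[[`, logical(1), "noise_present")))
  expect_lt(peaks[1], 50)               # early chunks below the center
  expect_gt(peaks[5], 50)               # late chunks above
  expect_true(all(diff(peaks) >= -1 / 55))  # monotone within resolution
})

test_that("a pure 1/f recording passes through unchanged with an empty report", {
  rec <- pink_background(6, 90, 250, seed = 53)
  res <- zap_clean(rec)
  expect_identical(res$clean$data, rec$data)
  expect_length(res$report$frequencies, 0)
  expect_length(res$report$final_config$noisefreqs, 0)
})

test_that("end-to-end cleaning detects and suppresses a planted 50 Hz source", {
  rec <- make_test_recording(10, 90, 250, f = 50, amplitude = 3, seed = 54)
  res <- zap_clean(rec)
  freqs <- vapply(res$report$frequencies, `[[`, numeric(1), "frequency")
  expect_length(freqs, 1)
  expect_lt(abs(freqs[1] - 50), 0.1)
  an <- res$report$frequencies[[1]]$analytics
  expect_gt(an$ratio_noise_to_surroundings_raw,
            an$ratio_noise_to_surroundings_clean)
  expect_lt(an$ratio_noise_to_surroundings_clean, 1.5)
  # conservation: raw = clean + removed, exactly as matrices
  removed <- rec$data - res$clean$data
  expect_lt(max(abs(rec$data - (res$clean$data + removed))), 1e-12)
  # report matrices have consistent per-chunk dimensions
  fr <- res$report$frequencies[[1]]
  nch <- length(fr$n_removed)
  expect_equal(ncol(fr$artifact_scores), nch)
  expect_length(fr$chunk_peak_frequency, nch)
  expect_length(fr$noise_present_flag, nch)
})

test_that("explicit noisefreqs skip detection but keep chunk-level machinery", {
  rec <- make_test_recording(10, 90, 250, f = 50, amplitude = 3, seed = 55)
  res <- zap_clean(rec, zap_config(noisefreqs = 50))
  expect_length(res$report$frequencies, 1)
  expect_equal(res$report$frequencies[[1]]$frequency, 50)
  expect_true(res$report$frequencies[[1]]$noise_present_flag[1])
  expect_false(identical(res$clean$data, rec$data))
})
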