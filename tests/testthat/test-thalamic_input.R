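test_that("gamma-filtered noise concentrates power in the passband", {
  x <- gamma_filtered_noise(10, dt = 1, center = 57, bandwidth = 10, seed = 4)
  expect_equal(sd(x), 1, tolerance = 1e-9)
  expect_lt(abs(mean(x)), 3 / sqrt(10 * 10))  # 3 SE for ~bandwidth dof
  p <- welch_psd(x, fs = 1000, window_ms = 1000, zscore = FALSE)
  inband <- sum(p$power[p$freq >= 52 & p$freq <= 62]) / sum(p$power)
  expect_gt(inband, 0.8)
})

test_that("the filtered-noise spectral peak follows the requested center", {
  # the band-pass response is flat-topped, so the robust location measure is
  # the spectral centroid of the averaged PSD around the passband
  for (ctr in c(50, 55, 60, 65)) {
    pows <- rowMeans(sapply(1:5, function(s) {
      x <- gamma_filtered_noise(10, dt = 1, center = ctr, seed = 7 + s)
      welch_psd(x, fs = 1000, window_ms = 1000, zscore = FALSE)$power
    }))
    freq <- welch_psd(gamma_filtered_noise(2, dt = 1, center = ctr, seed = 1),
                      fs = 1000, window_ms = 1000, zscore = FALSE)$freq
    sel <- freq >= ctr - 10 & freq <= ctr + 10
    centroid <- sum(freq[sel] * pows[sel]) / sum(pows[sel])
    expect_lt(abs(centroid - ctr), 2)
    # and the global argmax lies inside the passband
    expect_lt(abs(freq[which.max(pows)] - ctr), 6)
  }
})

test_that("invalid passbands are rejected", {
  expect_error(gamma_filtered_noise(2, dt = 1, center = 499, bandwidth = 10),
               "Nyquist")
  expect_error(gamma_filtered_noise(2, dt = 1, center = 4, bandwidth = 10),
               "0 Hz")
  expect_error(gamma_filtered_noise(0.05, dt = 1, center = 57, bandwidth = 10),
               "too short")
})

test_that("colored noise is z-scored with the requested spectral slope", {
  x <- colored_noise(10, dt = 1, exponent = 1.5, seed = 1)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 1, tolerance = 1e-12)
  slopes <- sapply(1:20, function(i) {
    x <- colored_noise(10, dt = 1, exponent = 1.5, seed = i)
    p <- welch_psd(x, fs = 1000, window_ms = 2000, zscore = FALSE)
    sel <- p$freq >= 1 & p$freq <= 100
    unname(coef(lm(log(p$power[sel]) ~ log(p$freq[sel])))[2])
  })
  expect_lt(abs(mean(slopes) + 1.5), 0.2)
  expect_error(colored_noise(1, exponent = -1), "invalid configuration")
})

test_that("the reversal envelope rises linearly then decays at 25 1/s", {
  expect_equal(reversal_envelope(0), 0)
  expect_equal(reversal_envelope(10), 1)
  expect_equal(reversal_envelope(50), exp(-1), tolerance = 1e-12)
  expect_equal(reversal_envelope(-5), 0)
  tt <- seq(-20, 400, by = 0.1)
  f <- reversal_envelope(tt)
  expect_equal(max(f), 1)
  expect_true(all(f >= 0 & f <= 1))
  expect_lt(reversal_envelope(210), 0.01)  # transient over within ~200 ms
})

test_that("the thalamic rate is rectified and stationary when static", {
  params <- thalamic_input_params(K = 30)
  expect_equal(params$A0, 0)
  expect_equal(params$S0, 500)
  r <- thalamic_rate(params, duration = 4, dt = 1, seed = 2)
  expect_true(all(r$rate >= 0))
  expect_equal(mean(r$rate), 500, tolerance = 0.1)  # rectification inflates slightly
  expect_true(all(r$A_t == 0))
  # forced rectification: tiny sustained rate with large noise
  low <- thalamic_input_params(K = NA, A0 = 0, alpha = 0, S0 = 10, beta = 0)
  rl <- thalamic_rate(low, duration = 2, dt = 1, seed = 3)
  expect_gt(mean(rl$rate == 0), 0.1)
  expect_true(all(rl$rate >= 0))
})

test_that("reversal-locked envelopes modulate S immediately and A after Dt", {
  params <- thalamic_input_params(K = 90, reversal_times = 1)
  r <- thalamic_rate(params, duration = 2, dt = 1, seed = 5)
  tt <- (seq_along(r$S_t) - 1)  # ms
  expect_equal(r$S_t[tt == 1010], 600 + 200, tolerance = 1e-9) # peak of f
  expect_lt(r$S_t[tt == 1250], 610)                            # relaxed
  expect_equal(r$S_t[tt == 500], 600)                          # pre-reversal
  p10 <- thalamic_input_params(K = 10, reversal_times = 1)
  r10 <- thalamic_rate(p10, duration = 2, dt = 1, seed = 5)
  expect_equal(r10$A_t[tt == 1020], 30)      # before the 40 ms latency
  expect_equal(r10$A_t[tt == 1050], 0, tolerance = 1e-9)  # dip peak at t*+Dt+10
  expect_equal(r10$A_t[tt == 500], 30)
})

test_that("the time-dependent generator reduces to the stationary one", {
  a <- thalamic_input_params(K = NA, A0 = 20, alpha = 0, S0 = 500, beta = 0,
                             reversal_times = c(0.5, 1.0))
  b <- thalamic_input_params(K = NA, A0 = 20, alpha = 0, S0 = 500, beta = 0)
  ra <- thalamic_rate(a, duration = 1.5, dt = 1, seed = 9)
  rb <- thalamic_rate(b, duration = 1.5, dt = 1, seed = 9)
  expect_identical(ra$rate, rb$rate)
})

test_that("alpha must not exceed A0 and negatives are rejected", {
  expect_error(thalamic_input_params(K = NA, A0 = 10, alpha = 20, S0 = 500,
                                     beta = 0), "alpha")
  expect_error(thalamic_input_params(K = NA, A0 = -1, alpha = 0, S0 = 500,
                                     beta = 0), "non-negative")
})

test_that("Poisson input spike trains have matching moments", {
  raster <- draw_input_spikes(500, n_neurons = 1000, duration = 2, dt = 0.05,
                              seed = 10)
  counts <- tabulate(raster$neuron, 1000)
  expect_equal(mean(counts), 1000, tolerance = 0.02)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.15)  # Fano ~ 1
  expect_equal(length(draw_input_spikes(0, 10, duration = 1)$time_ms), 0)
  r1 <- draw_input_spikes(500, 2, duration = 1, seed = 1)
  t1 <- r1$time_ms[r1$neuron == 1]
  t2 <- r1$time_ms[r1$neuron == 2]
  expect_false(identical(t1, t2))
})

test_that("rate spectra peak inside the oscillation band when A > 0", {
  params <- thalamic_input_params(K = NA, A0 = 100, alpha = 0, S0 = 500,
                                  beta = 0, noise_amplitude = 0.05)
  r <- thalamic_rate(params, duration = 8, dt = 1, seed = 21)
  p <- welch_psd(r$rate - mean(r$rate), fs = 1000, window_ms = 1000,
                 zscore = FALSE)
  pk <- p$freq[-1][which.max(p$power[-1])]
  expect_gte(pk, 52)
  expect_lte(pk, 62)
})

test_that("the shipped parameter table carries the six contrast rows", {
  tab <- thalamic_table()
  expect_equal(tab$K, c(0, 10, 20, 30, 50, 90))
  expect_equal(tab$A, tab$A0)  # stationary amplitudes equal baselines
  expect_true(all(tab$alpha <= tab$A0))
})
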