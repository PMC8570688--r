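test_that("Welch PSD localizes tones and conserves variance", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  p <- welch_psd(lfp_trace(sin(2 * pi * 60 * t), fs))
  expect_equal(p$freq[which.max(p$power)], 60)
  # Parseval: integral of the one-sided density ~ variance of the z-scored trace
  set.seed(1)
  pw <- welch_psd(lfp_trace(rnorm(10000), fs))
  expect_equal(sum(pw$power) * (pw$freq[2] - pw$freq[1]), 1, tolerance = 0.1)
  # equal-amplitude tones give equal peaks within estimator tolerance
  x2 <- sin(2 * pi * 30 * t) + sin(2 * pi * 60 * t)
  p2 <- welch_psd(lfp_trace(x2, fs))
  pk30 <- p2$power[p2$freq == 30]
  pk60 <- p2$power[p2$freq == 60]
  expect_equal(pk30 / pk60, 1, tolerance = 0.05)
  expect_error(welch_psd(lfp_trace(rnorm(100), fs), window_ms = 500), "shorter")
})

test_that("short segments use a single whole-segment window", {
  x <- lfp_trace(rnorm(200), 1000)  # 200 ms at 1 kHz
  p <- welch_psd(x, window_ms = NULL)
  expect_equal(p$window_ms, 200)
  expect_equal(p$freq[2] - p$freq[1], 5)  # 1/0.2 s resolution
})

test_that("dB conversion round-trips", {
  p <- abs(rnorm(50)) + 0.1
  expect_equal(db_to_power(power_to_db(p)), p, tolerance = 1e-12)
})

test_that("PSD modulation is the pointwise relative power change", {
  ref <- c(1, 2, 4)
  expect_equal(psd_modulation(ref, ref)$modulation, c(0, 0, 0))
  expect_equal(psd_modulation(2 * ref, ref)$modulation, c(1, 1, 1))
  expect_equal(psd_modulation(0.5 * ref, ref)$modulation, c(-0.5, -0.5, -0.5))
  for (r in c(0.1, 0.7, 3.3)) {
    expect_equal(psd_modulation(r * ref, ref)$modulation, rep(r - 1, 3),
                 tolerance = 1e-12)
  }
  expect_error(psd_modulation(c(1, 2), c(1, 0)), "degenerate")
  p1 <- welch_psd(lfp_trace(rnorm(1000), 1000))
  p2 <- welch_psd(lfp_trace(rnorm(1000), 1000), window_ms = 250)
  expect_error(psd_modulation(p1, p2), "grids|lengths")
})

test_that("the Morse scalogram tracks stationary and swept frequencies", {
  fs <- 1000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  sc <- morse_scalogram(sin(2 * pi * 60 * t), fs = fs)
  interior <- sc$time_ms > 200 & sc$time_ms < 800
  ridge <- sc$freq[apply(sc$magnitude[, interior], 2, which.max)]
  expect_true(all(abs(ridge - 60) / 60 < 0.07))  # within one voice step
  # linear chirp 40 -> 80 Hz over 1 s: instantaneous frequency 40 + 40 t
  chirp <- sin(2 * pi * (40 * t + 20 * t^2))
  scc <- morse_scalogram(chirp, fs = fs)
  for (tm in c(300, 500, 700)) {
    col <- which.min(abs(scc$time_ms - tm))
    f_inst <- 40 + 40 * tm / 1000
    f_ridge <- scc$freq[which.max(scc$magnitude[, col])]
    expect_lt(abs(f_ridge - f_inst) / f_inst, 0.1)
  }
})

test_that("scalogram magnitude is linear in signal amplitude", {
  fs <- 1000
  t <- seq(-1, 1 - 1 / fs, by = 1 / fs)
  x <- ifelse(t < 0, 1, 2) * sin(2 * pi * 60 * t)
  sc <- morse_scalogram(x, fs = fs)
  nb <- sc$freq >= 55 & sc$freq <= 65
  before <- mean(sc$magnitude[nb, sc$time_ms > 300 & sc$time_ms < 700])
  after <- mean(sc$magnitude[nb, sc$time_ms > 1300 & sc$time_ms < 1700])
  expect_equal(after / before, 2, tolerance = 0.05)
})

test_that("scalogram and Welch agree on a stationary tone peak", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 57 * t) + 0.2 * rnorm(length(t))
  pw <- peak_frequency(welch_psd(lfp_trace(x, fs)), c(40, 75))
  sc <- morse_scalogram(x, fs = fs)
  ridge <- sc$freq[which.max(rowMeans(sc$magnitude))]
  expect_lt(abs(ridge - pw), 3)
})

test_that("reversal segmentation averages windows and respects exclusions", {
  fs <- 1000
  x <- rnorm(3000)
  sc <- morse_scalogram(x, fs = fs)
  seg <- segment_scalogram(sc, reversal_times_s = c(0.2, 1.0, 1.5, 2.0))
  expect_equal(seg$n_segments, 3)  # the 0.2 s reversal is onset-excluded
  expect_equal(range(seg$time_ms), c(-100, 400))
  expect_error(segment_scalogram(sc, reversal_times_s = 2.9), "segmentation")
  expect_error(segment_scalogram(sc, reversal_times_s = 0.2), "segmentation")
})

test_that("band limits derive from the threshold rule", {
  f <- seq(10, 110, by = 0.5)
  m <- ifelse((f >= 20 & f <= 45) | (f >= 65 & f <= 95), 0.5,
              ifelse(f > 45 & f < 65, -0.3, 0))
  bd <- derive_band_limits(f, m, 0.2)
  expect_false(bd$empty)
  expect_equal(bd$nb, c(45, 65))
  expect_equal(unname(bd$bb[1, ]), c(20, 45))
  expect_equal(unname(bd$bb[2, ]), c(65, 95))
  # no super-threshold frequencies: flagged, not an error
  expect_true(derive_band_limits(f, rep(0, length(f)))$empty)
  # triangular profile: 0.2-crossings of a triangle peaking at 0.4 at 30 Hz
  tri <- pmax(0.4 - 0.02 * abs(f - 30), 0)
  bt <- derive_band_limits(f, tri, 0.2)
  expect_equal(unname(bt$bb[1, ]), c(20.5, 39.5), tolerance = 0.11)
})

test_that("default bands partition the gamma range", {
  bd <- default_bands()
  expect_equal(bd$nb, c(45, 65))
  expect_equal(sort(c(bd$nb, bd$bb)), c(20, 45, 45, 65, 65, 95))
})

test_that("band time courses reduce the modulation map by band medians", {
  freq <- seq(20, 95, by = 5)
  time_ms <- seq(-100, 400, by = 2)
  flat <- list(freq = freq, time_ms = time_ms,
               magnitude = matrix(0.3, length(freq), length(time_ms)))
  tc <- band_timecourse(flat, c(45, 65))
  expect_true(all(tc$values == 0.3))
  outside <- flat
  outside$magnitude[freq >= 45 & freq <= 65, ] <- 0
  tc2 <- band_timecourse(outside, c(45, 65))
  expect_true(all(tc2$values == 0))
  # synthetic BB bump peaking at 76 ms is recovered at 76 ms
  bump <- flat
  bump$magnitude[] <- 0
  gauss <- 0.46 * exp(-((time_ms - 76) / 40)^2)
  for (i in which(freq < 45 | freq > 65)) bump$magnitude[i, ] <- gauss
  tc3 <- band_timecourse(bump, rbind(c(20, 45), c(65, 95)))
  expect_equal(tc3$time_ms[which.max(tc3$values)], 76)
  expect_equal(max(tc3$values), 0.46, tolerance = 1e-9)
})
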