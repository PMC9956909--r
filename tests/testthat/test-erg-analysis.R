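test_that("band-pass keeps the passband, rejects DC and the stopband, zero phase", {
  rate <- 1024
  t <- (0:8191) / rate
  mid <- 3000:5000

  x100 <- sin(2 * pi * 100 * t)
  y100 <- bandpass_filter(x100, rate)
  expect_lt(abs(max(abs(y100[mid])) - 1), 0.05)    # 100 Hz within 5%
  # zero phase: the steady-state output tracks the input sample for sample
  expect_lt(max(abs(y100[mid] - x100[mid])), 0.05)

  expect_lt(max(abs(bandpass_filter(rep(5, 8192), rate)[mid])), 0.05)  # DC

  y500 <- bandpass_filter(sin(2 * pi * 500 * t), rate)
  expect_lt(max(abs(y500[mid])), 10^(-20 / 20))    # > 20 dB down at 500 Hz

  expect_length(y100, 8192L)
  expect_error(bandpass_filter(x100, rate, low = 0), "Band edges")
  expect_error(bandpass_filter(x100, rate, low = 10, high = 600), "Band edges")
})

test_that("average_sweeps is the pointwise sweep mean", {
  n <- 64
  one <- matrix(rep(sin(seq_len(n) / 5), each = 20), nrow = 20, byrow = FALSE)
  rec <- erg_recording("e", "left", "scotopic", 1024, 10,
                       luminances = c(1, 2),
                       sweeps = list(one, rbind(one[1, ], -one[1, ])))
  expect_equal(average_sweeps(rec, 1), one[1, ])          # identical sweeps
  expect_equal(average_sweeps(rec, 2), rep(0, n))         # s and -s cancel
  set.seed(42)
  rnd <- matrix(rnorm(20 * n), 20, n)
  rec$sweeps[[1]] <- rnd
  oracle <- vapply(seq_len(n), function(j) sum(rnd[, j]) / 20, numeric(1))
  expect_equal(average_sweeps(rec, 1), oracle)
  expect_error(average_sweeps(rec, 99), "not present")
})

test_that("measure_waves reads amplitudes and implicit times off a constructed trace", {
  # rate 1000 so extrema land exactly on samples: trough -150 uV at 15 ms,
  # peak +200 uV at 35 ms, baseline 0
  rate <- 1000
  onset <- 101L
  t_ms <- (seq_len(300) - onset) / rate * 1000
  trace <- approx(x = c(-100, 0, 15, 35, 100, 199),
                  y = c(0, 0, -150, 200, 0, 0), xout = t_ms)$y
  res <- measure_waves(trace, onset, rate)
  expect_equal(res$a_amplitude, 150)
  expect_equal(res$b_amplitude, 350)
  expect_equal(res$a_implicit, 15)
  expect_equal(res$b_implicit, 35)
  expect_true(res$a_detected && res$b_detected)
  expect_equal(res$baseline, 0)

  # constant offset shifts baseline and extrema alike: amplitudes unchanged
  res_off <- measure_waves(trace + 250, onset, rate)
  expect_identical(res_off$a_amplitude, res$a_amplitude)
  expect_identical(res_off$b_amplitude, res$b_amplitude)
  expect_equal(res_off$baseline, 250)
})

test_that("an all-zero trace yields no detected waves and no implicit times", {
  res <- measure_waves(rep(0, 300), 101L, 1000)
  expect_false(res$a_detected)
  expect_false(res$b_detected)
  expect_true(is.na(res$a_implicit))
  expect_true(is.na(res$b_implicit))
})

test_that("excursions below the noise threshold are flagged undetected", {
  rate <- 1000
  onset <- 101L
  trace <- rep(0, 300)
  trace[(onset - 10):(onset - 1)] <- rep(c(5, -5), 5)  # baseline SD ~ 5 uV
  noise_sd <- sd(trace[(onset - 10):(onset - 1)])
  small <- trace; small[onset + 15] <- -10              # < 3 x SD: undetected
  res <- measure_waves(small, onset, rate)
  expect_false(res$a_detected)
  expect_true(is.na(res$a_implicit))
  big <- trace; big[onset + 15] <- -(3 * noise_sd + 5)  # clears the threshold
  res2 <- measure_waves(big, onset, rate)
  expect_true(res2$a_detected)
  expect_equal(res2$noise_sd_estimate, noise_sd)
})

test_that("b-wave falls back to baseline reference when no a-trough is detected", {
  rate <- 1000
  onset <- 101L
  t_ms <- (seq_len(300) - onset) / rate * 1000
  trace <- ifelse(t_ms > 0, 200 * exp(-0.5 * ((t_ms - 35) / 10)^2), 0)
  res <- measure_waves(trace, onset, rate)
  expect_false(res$a_detected)
  expect_true(res$b_detected)
  expect_identical(res$b_reference, "baseline")
  expect_equal(res$b_amplitude, 200, tolerance = 0.01)
})

test_that("measure_waves rejects traces too short for the search windows", {
  expect_error(measure_waves(rep(0, 120), 101L, 1000), "shorter")
  expect_error(measure_waves(rep(0, 300), 5L, 1000), "pre-stimulus")
})

test_that("analyze_recording measures every flash strength in ascending order", {
  sim <- simulate_erg_sweeps(erg_model_params(noise_sd = 10, seed = 6),
                             erg_protocol("scotopic"))
  res <- analyze_recording(sim$recording)
  expect_equal(nrow(res), 9L)
  expect_false(is.unsorted(res$luminance, strictly = TRUE))
  expect_identical(res$eye_id, rep("sim-eye", 9))
})

test_that("sub-noise lowest flash steps are flagged undetected, strong steps detected", {
  # expected a-wave at 0.001 cd.s/m2 is ~3 uV against ~2 uV averaged noise
  sim <- simulate_erg_sweeps(erg_model_params(noise_sd = 10, seed = 7),
                             erg_protocol("scotopic"))
  res <- analyze_recording(sim$recording)
  expect_false(res$a_detected[1])
  expect_true(all(res$a_detected[res$luminance >= 0.1]))
  expect_true(all(res$b_detected[res$luminance >= 0.1]))
  expect_true(all(is.na(res$a_implicit[!res$a_detected])))
})

test_that("a-trough precedes b-peak whenever both waves are detected", {
  for (seed in 1:8) {
    sim <- simulate_erg_sweeps(erg_model_params(noise_sd = 10, seed = seed),
                               erg_protocol("scotopic", n_repeats = 10))
    res <- analyze_recording(sim$recording)
    both <- res$a_detected & res$b_detected
    expect_true(all(res$a_implicit[both] < res$b_implicit[both]))
  }
})

test_that("averaging 20 sweeps shrinks the noise by about sqrt(20)", {
  pars <- erg_model_params(noise_sd = 10, seed = 8)
  proto <- erg_protocol("scotopic")
  sim <- simulate_erg_sweeps(pars, proto)
  clean <- simulate_erg_sweeps(
    erg_model_params(noise_sd = 0, seed = 8), proto)
  resid <- vapply(seq_len(9), function(i) {
    sd(colMeans(sim$recording$sweeps[[i]]) - clean$recording$sweeps[[i]][1, ])
  }, numeric(1))
  expect_true(all(abs(resid / (10 / sqrt(20)) - 1) < 0.2))
})
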