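test_that("call rate is the reciprocal onset-to-onset interval", {
  expect_equal(call_rate(c(0, 4, 10)), c(0.25, 1 / 6, NA))
  expect_equal(call_rate(seq(0, 45, by = 5)), c(rep(0.2, 9), NA))
  expect_error(call_rate(c(0, 0, 5)), "strictly increasing")
  expect_error(call_rate(3), "at least two")

  # mean rate equals the brute-force mean of reciprocals
  set.seed(21)
  for (i in 1:100) {
    onsets <- cumsum(runif(sample(3:20, 1), 0.5, 8))
    r <- call_rate(onsets)
    brute <- mean(1 / diff(onsets))
    expect_equal(mean(r, na.rm = TRUE), brute)
  }
})

test_that("call effort is duration x rate with the final call excluded", {
  expect_equal(call_effort(0.6, 0.25), 0.15)
  eff <- call_effort(c(0.5, 0.6), c(0.3, NA))
  expect_true(is.na(eff[2]))
  # duration equal to the inter-onset interval saturates at 1
  on <- c(0, 2, 4)
  dur <- c(2, 2, 1)
  expect_equal(call_effort(dur, call_rate(on))[1:2], c(1, 1))
})

test_that("recording means are invariant to event-table row order", {
  set.seed(22)
  on <- cumsum(runif(30, 2, 8))
  ev <- data.frame(recording_id = "r1", call_idx = 1:30, onset_s = on,
                   offset_s = on + runif(30, 0.3, 0.8),
                   pulse_count = sample(20:40, 30, TRUE),
                   domfreq_hz = rnorm(30, 2400, 50))
  f1 <- recording_features(ev)
  f2 <- recording_features(ev[sample(30), ])
  expect_equal(f1, f2)
  expect_equal(f1$n_calls, 30)
  # rate/effort means use n-1 calls
  expect_equal(f1$call_rate, mean(1 / diff(on)))
  expect_equal(f1$call_effort,
               mean((ev$offset_s - ev$onset_s)[1:29] / diff(on)))
})

test_that("inter-observer reliability returns r and OLS slope", {
  a <- c(1, 2, 3, 4, 5)
  same <- interobserver_reliability(a, a)
  expect_equal(same$r, 1)
  expect_equal(same$slope, 1)
  doubled <- interobserver_reliability(a, 2 * a)
  expect_equal(doubled$r, 1)
  expect_equal(doubled$slope, 2)
  expect_error(interobserver_reliability(rep(1, 5), a), "zero variance")

  # bivariate normal with true correlation 0.9, n = 2758
  set.seed(23)
  n <- 2758
  x <- rnorm(n)
  y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(n)
  est <- interobserver_reliability(x, y)
  expect_equal(est$r, 0.9, tolerance = 0.05 / 0.9)
  expect_equal(est$n, n)

  # two simulated observers of the same calls agree closely
  co <- simulate_cohort(cohort_params(n_individuals = 12, seed = 24))
  ev <- simulate_calls(co, seed = 24)$events
  ev2 <- simulate_observer_remeasure(ev, seed = 25)
  dur <- interobserver_reliability(ev$offset_s - ev$onset_s,
                                   ev2$offset_s - ev2$onset_s)
  expect_gt(dur$r, 0.9)
  expect_equal(dur$slope, 1, tolerance = 0.1)
})

test_that("audio segmentation recovers generator calls", {
  p <- call_sim_params()
  # single synthesized call: 30 pulses at 50 s^-1, 2400 Hz, 20 dB SNR
  set.seed(26)
  call <- simulate_call_audio(30, 50, 2400, 44100)
  wave <- c(numeric(44100), call, numeric(44100))
  wave <- wave + rnorm(length(wave), 0, sqrt(mean(call[call != 0]^2)) / 10)
  det <- extract_from_audio(wave, 44100)
  expect_equal(nrow(det), 1)
  expect_equal(det$pulse_count, 30)
  expect_equal(det$domfreq_hz, 2400, tolerance = (44100 / 2048) / 2400)

  # pure silence -> no calls
  expect_equal(nrow(extract_from_audio(numeric(44100), 44100)), 0)
  set.seed(27)
  expect_equal(nrow(extract_from_audio(rnorm(44100, 0, 1e-3), 44100)), 0)
})

test_that("a synthesized bout round-trips through audio extraction", {
  # 30 calls at 11 calls/min -> mean rate 0.1833 s^-1
  n <- 30
  onsets <- (0:(n - 1)) * (60 / 11)
  ev <- data.frame(recording_id = "b1", call_idx = 1:n, onset_s = onsets,
                   offset_s = onsets + 0.6,
                   pulse_count = sample(25:35, n, TRUE),
                   domfreq_hz = 2400)
  bout <- simulate_bout_audio(ev, call_sim_params(), seed = 28)
  det <- extract_from_audio(bout$wave, bout$fs)
  expect_equal(nrow(det), n)
  expect_equal(det$pulse_count, ev$pulse_count)
  feats <- recording_features(det)
  expect_equal(feats$call_rate, 11 / 60, tolerance = 1e-3)
  # duration recovered within 10 ms of the acoustic extent
  extent <- (ev$pulse_count - 1) / 50 + 0.7 / 50
  expect_true(all(abs((det$offset_s - det$onset_s) - extent) < 0.010))
})

test_that("pulse counting is exact up to 80 pulses per second at 20 dB", {
  for (rate in c(40, 60, 80)) {
    set.seed(rate)
    call <- simulate_call_audio(24, rate, 2400, 44100)
    pad <- numeric(22050)
    wave <- c(pad, call, pad) +
      rnorm(length(call) + 44100, 0, sqrt(mean(call[call != 0]^2)) / 10)
    det <- extract_from_audio(wave, 44100)
    expect_equal(nrow(det), 1)
    expect_equal(det$pulse_count, 24)
  }
})

test_that("WAV files round-trip at 16-bit precision", {
  set.seed(29)
  w <- c(numeric(22050), simulate_call_audio(10), numeric(22050))
  w <- w + rnorm(length(w), 0, 1e-3)
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, f, 44100)
  back <- read_wav(f)
  expect_equal(back$fs, 44100)
  expect_lt(max(abs(back$wave - w)), 1 / 32767)  # half-LSB quantization
  det <- extract_from_audio(f)
  expect_equal(det$pulse_count, 10)
})
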