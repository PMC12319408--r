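test_that("flow correction matches its closed form and is monotone", {
  expect_equal(correct_flow(100, 101.3, 0), 100)
  expect_equal(correct_flow(100, 101.3, 2.0), 98.02567, tolerance = 1e-6)
  expect_error(correct_flow(100, 101.3, 101.3), "WVP < BP")
  # FR_d <= FR whenever WVP >= 0
  wvp <- seq(0, 4, by = 0.5)
  expect_true(all(correct_flow(100, 101.3, wvp) <= 100))
  expect_true(all(diff(correct_flow(100, 101.3, wvp)) < 0))
})

test_that("VO2 equation matches direct evaluation and is monotone", {
  p <- reduction_params()
  expect_equal(compute_vo2(0, 100, p), 0)
  # FR_d = 98.026, dO2 = 5e-4: FeO2 = 0.2090, denominator 0.791
  expect_equal(compute_vo2(5e-4, 98.02567, p), 3.71779, tolerance = 1e-5)
  expect_error(compute_vo2(0.21, 100, p), "fio2_ref")
  d <- seq(0, 0.005, by = 5e-4)
  expect_true(all(diff(compute_vo2(d, 100, p)) > 0))
  expect_true(all(compute_vo2(0.001, seq(50, 200, 25), p) ==
                    cummax(compute_vo2(0.001, seq(50, 200, 25), p))))
})

test_that("injected analyzer lag is recovered and bounds are flagged", {
  sim <- simulate_trace(0.9, noiseless_trace_params(lag_s = 5), seed = 2)
  al <- correct_lag(sim$trace, reduction_params(lag_max_s = 30))
  lg <- attr(al, "lag")
  expect_equal(lg$o2_pct$lag, 5)
  expect_equal(lg$o2_pct$flag, "ok")
  expect_equal(lg$co2_pct$lag, 5)

  # zero injected lag -> zero estimated shift
  sim0 <- simulate_trace(0.9, noiseless_trace_params(), seed = 2)
  lg0 <- attr(correct_lag(sim0$trace), "lag")
  expect_equal(lg0$o2_pct$lag, 0)

  # lag beyond the search bound: flagged, left uncorrected
  simb <- simulate_trace(0.9, noiseless_trace_params(lag_s = 5), seed = 2)
  alb <- correct_lag(simb$trace, reduction_params(lag_max_s = 3))
  expect_equal(attr(alb, "lag")$o2_pct$flag, "lag_at_bound")
  expect_equal(alb$o2_pct, simb$trace$o2_pct)

  # flat channels: lag undeterminable
  base <- make_tiny_trace(600)
  tr <- respirometry_trace(base$time_s, rep(20.95, 600), base$co2_pct,
                           rep(1.5, 600), base$bp_kpa, base$fr_ml_min,
                           base$channel)
  lgf <- attr(correct_lag(tr), "lag")
  expect_equal(lgf$o2_pct$flag, "flat")
  expect_equal(lgf$o2_pct$lag, 0)
})

test_that("baseline correction removes a linear drift in closed form", {
  # O2 drifts linearly 20.95 -> 20.90 across three segments; animal
  # deflection 0.05% below the drift line -> dO2 = 5e-4 exactly
  n <- 2700
  t <- 0:(n - 1)
  drift <- 20.95 - 0.05 * t / (n - 1)
  chan <- rep(c(0L, 1L, 0L), each = 900)
  o2 <- drift - 0.05 * (chan == 1L)
  tr <- respirometry_trace(t, o2, rep(0.04, n), rep(1.5, n), rep(101.3, n),
                           rep(100, n), chan)
  sch <- infer_schedule(tr)
  d <- baseline_correct(tr, sch, reduction_params(washout_s = 0))
  animal <- chan == 1L
  expect_equal(d$delta_o2[animal], rep(5e-4, sum(animal)), tolerance = 1e-12)
  expect_false(any(d$extrapolated[animal]))

  # no drift, no animal -> dO2 identically 0
  tr0 <- respirometry_trace(t, rep(20.95, n), rep(0.04, n), rep(1.5, n),
                            rep(101.3, n), rep(100, n), chan)
  d0 <- baseline_correct(tr0, infer_schedule(tr0), reduction_params())
  expect_equal(d0$delta_o2, rep(0, n))

  # needs two baseline segments
  tr1 <- respirometry_trace(t[1:1800], o2[1:1800], rep(0.04, 1800),
                            rep(1.5, 1800), rep(101.3, 1800),
                            rep(100, 1800), chan[1:1800])
  expect_error(baseline_correct(tr1, infer_schedule(tr1)),
               ">= 2 baseline")
})

test_that("baseline residuals on noisy traces stay below the noise SD", {
  sim <- simulate_trace(rep(0.9, 3), trace_sim_params(burst_prob = 0),
                        seed = 9)
  sch <- infer_schedule(sim$trace)
  d <- baseline_correct(sim$trace, sch, reduction_params())
  base <- sim$trace$channel == 0L
  # drift removed: per-baseline-segment means are ~0 at the noise scale
  resid <- d$delta_o2[base] * 100
  expect_lt(abs(mean(resid)), 0.00027)
})

test_that("reduce_trial recovers constant true VO2 and repetition structure", {
  sim <- simulate_trace(rep(0.9, 2), noiseless_trace_params(), seed = 4)
  series <- reduce_trial(sim$trace, params = reduction_params())
  chans <- vapply(series, attr, integer(1), "channel")
  reps <- vapply(series, attr, integer(1), "repetition")
  expect_equal(sum(chans == 1), 3)  # three repetitions per animal channel
  expect_equal(sort(unname(reps[chans == 2])), 1:3)
  for (s in series) {
    expect_equal(mean(s$vo2_ml_h), 0.9, tolerance = 1e-6)
  }
})

test_that("recovered VO2 is invariant to flow within 1%", {
  means <- vapply(c(50, 100, 200), function(fr) {
    sim <- simulate_trace(0.9, noiseless_trace_params(flow_ml_min = fr),
                          seed = 5)
    s <- reduce_trial(sim$trace, params = reduction_params())
    mean(vapply(s, function(r) mean(r$vo2_ml_h), numeric(1)))
  }, numeric(1))
  expect_true(all(abs(means - 0.9) / 0.9 < 0.01))
})

test_that("linear O2 drift up to +/-0.05 %/h shifts means by < 2%", {
  ref <- simulate_trace(0.9, noiseless_trace_params(), seed = 6)
  base_means <- vapply(reduce_trial(ref$trace), function(r)
    mean(r$vo2_ml_h), numeric(1))
  for (dr in c(-0.05, 0.05)) {
    sim <- simulate_trace(0.9, noiseless_trace_params(drift_o2_pct_h = dr),
                          seed = 6)
    m <- vapply(reduce_trial(sim$trace), function(r) mean(r$vo2_ml_h),
                numeric(1))
    expect_true(all(abs(m - base_means) / base_means < 0.02))
  }
})
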