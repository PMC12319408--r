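make_stat_trials <- function(seed = 1, ...) {
  co <- simulate_cohort(cohort_params(seed = seed, ...))
  tr <- co$trials
  tr$rmr_ml_o2_h <- tr$true_rmr
  list(cohort = co, trials = tr)
}

test_that("RMR model recovers generating slopes within 2 standard errors", {
  # averaged over three independent cohorts: the mean estimate should sit
  # within 2 * se / sqrt(3) of the generating value
  fits <- lapply(101:103, function(s)
    fit_rmr_model(make_stat_trials(seed = s)$trials, "linear"))
  for (chk in list(c("calendar_day", -0.01), c("mass_g", 0.18),
                   c("year2024", -0.24))) {
    est <- vapply(fits, function(m) {
      m$coefficients$estimate[m$coefficients$term == chk[1]]
    }, numeric(1))
    se <- vapply(fits, function(m) {
      m$coefficients$se[m$coefficients$term == chk[1]]
    }, numeric(1))
    expect_lt(abs(mean(est) - as.numeric(chk[2])),
              2 * mean(se) / sqrt(3))
  }
  expect_equal(fits[[1]]$n_obs,
               nrow(make_stat_trials(seed = 101)$trials))
})

test_that("model variants expose quadratic-day and log-log structures", {
  tr <- make_stat_trials(seed = 102)$trials
  mq <- fit_rmr_model(tr, "quadratic-day")
  expect_true(any(grepl("scale\\(calendar_day\\)", mq$coefficients$term)))
  # generated decline is linear, so the quadratic term is null
  quad <- mq$coefficients[grepl("\\^2", mq$coefficients$term), ]
  expect_gt(quad$p, 0.05)
  ml <- fit_rmr_model(tr, "log10")
  expect_true(any(grepl("log10\\(mass_g\\)", ml$coefficients$term)))
})

test_that("year is coded against the 2023 reference on balanced data", {
  set.seed(103)
  n <- 80
  d <- data.frame(
    individual_id = sprintf("i%02d", 1:n),
    calendar_day = rep(165, n), mass_g = rep(5, n),
    year = rep(c(2023, 2024), each = n / 2))
  d$rmr_ml_o2_h <- 1 + -0.3 * (d$year == 2024) + rnorm(n, 0, 0.05)
  # duplicate each row so the random effect is identifiable
  d2 <- rbind(d, transform(d, rmr_ml_o2_h = rmr_ml_o2_h + rnorm(n, 0, 0.05)))
  # day and mass are constants here, so lme4 warns while dropping them
  m <- suppressWarnings(suppressMessages(fit_rmr_model(d2, "linear")))
  yr <- m$coefficients[m$coefficients$term == "year2024", ]
  means <- tapply(d2$rmr_ml_o2_h, d2$year, mean)
  expect_equal(yr$estimate, unname(means["2024"] - means["2023"]),
               tolerance = 1e-6)
})

test_that("call models are null for RMR and recover the mass slope", {
  s <- make_stat_trials(seed = 104)
  calls <- simulate_calls(s$cohort, seed = 104)
  feats <- merge(calls$recordings, recording_features(calls$events),
                 by = "recording_id")
  feats$rmr_ml_o2_h <- feats$true_rmr
  fits <- fit_call_models(feats)
  expect_named(fits, c("duration_s", "pulse_number", "domfreq_hz",
                       "call_rate", "call_effort"))
  # dominant frequency: generated mass slope recovered within 2 se
  cf <- fits$domfreq_hz$coefficients
  mass <- cf[cf$term == "mass_g", ]
  expect_lt(abs(mass$estimate - (-63.96)), 2 * mass$se)
  # temperature slope on duration: negative and significant
  cfd <- fits$duration_s$coefficients
  tmp <- cfd[cfd$term == "temp_c", ]
  expect_lt(tmp$estimate, 0)
  expect_lt(tmp$p, 0.001)
})

test_that("the RMR term has nominal type-I error when its effect is zero", {
  # re-simulate calls (null RMR effect) over a fixed cohort; the RMR
  # coefficient's p should be uniform: rejection rate ~5% at alpha = 0.05
  s <- make_stat_trials(seed = 105, n_individuals = 60)
  n_rep <- 150
  pvals <- vapply(seq_len(n_rep), function(i) {
    calls <- simulate_calls(s$cohort, seed = 20000 + i)
    feats <- merge(calls$recordings, recording_features(calls$events),
                   by = "recording_id")
    feats$rmr_ml_o2_h <- feats$true_rmr
    f <- fit_call_models(feats, traits = "duration_s")$duration_s
    f$coefficients$p[f$coefficients$term == "rmr_ml_o2_h"]
  }, numeric(1))
  rej <- mean(pvals < 0.05)
  expect_gt(rej, 0.005)  # binomial 99% band around 0.05 at n = 150
  expect_lt(rej, 0.12)
})

test_that("repeatability matches its defining variance ratio", {
  # individuals identical within, distinct between, tiny residual -> R ~ 1
  set.seed(106)
  d <- data.frame(individual_id = rep(sprintf("i%02d", 1:20), each = 3))
  d$y <- rep(rnorm(20, 0, 1), each = 3) + rnorm(60, 0, 1e-3)
  r1 <- repeatability(d, "y", n_boot = 0, seed = 1)
  expect_gt(r1$R, 0.99)
  expect_lt(r1$p_lrt, 1e-6)
  # R equals V_ind / (V_ind + V_res) from the same fit
  expect_equal(r1$R, r1$v_ind / (r1$v_ind + r1$v_res))

  # no repeated measures -> undefined
  d2 <- data.frame(individual_id = sprintf("i%02d", 1:10), y = rnorm(10))
  expect_error(repeatability(d2, "y", n_boot = 0, seed = 1),
               "repeated measures")
})

test_that("R is invariant to affine rescaling of the response", {
  tr <- make_stat_trials(seed = 107)$trials
  r1 <- repeatability(tr, "rmr_ml_o2_h", c("mass_g", "calendar_day"),
                      n_boot = 0, seed = 2)
  tr$scaled <- 100 * tr$rmr_ml_o2_h - 7
  r2 <- repeatability(tr, "scaled", c("mass_g", "calendar_day"),
                      n_boot = 0, seed = 2)
  expect_equal(r1$R, r2$R, tolerance = 1e-6)
})

test_that("bootstrap CI brackets the point estimate and is seeded", {
  tr <- make_stat_trials(seed = 108)$trials
  r <- repeatability(tr, "rmr_ml_o2_h", c("mass_g", "calendar_day"),
                     n_boot = 100, seed = 3)
  expect_true(r$ci_lower <= r$R && r$R <= r$ci_upper)
  r2 <- repeatability(tr, "rmr_ml_o2_h", c("mass_g", "calendar_day"),
                      n_boot = 100, seed = 3)
  expect_identical(r$ci_lower, r2$ci_lower)
})

test_that("the boundary LRT is conservative under the null", {
  # V_ind = 0 world: p-values should be super-uniform
  set.seed(109)
  n_rep <- 150
  p <- vapply(seq_len(n_rep), function(i) {
    d <- data.frame(
      individual_id = rep(sprintf("i%02d", 1:40), times = 2),
      x = rnorm(80))
    d$y <- 0.5 * d$x + rnorm(80)
    repeatability(d, "y", "x", n_boot = 0, seed = 1)$p_lrt
  }, numeric(1))
  expect_lte(mean(p < 0.05), 0.08)
  expect_lte(mean(p < 0.25), 0.30)
})

test_that("consistency regression behaves on degenerate and tracking data", {
  # identical RMR on consecutive days -> zero slope and intercept
  d <- data.frame(
    individual_id = rep(sprintf("i%02d", 1:10), each = 2),
    rmr_ml_o2_h = rep(runif(10, 0.5, 1.5), each = 2),
    calendar_day = rep(c(150, 151), 10), year = 2023)
  c0 <- consistency_analysis(d)
  expect_equal(c0$beta, 0)
  expect_equal(c0$intercept, 0)
  expect_equal(c0$n, 10)

  # deterministic seasonal decline tracked exactly by every individual:
  # raw slope positive, day-residualized slope ~ 0
  set.seed(110)
  first <- sample(130:180, 25, TRUE)
  gap <- sample(5:45, 25, TRUE)
  d2 <- data.frame(
    individual_id = rep(sprintf("i%02d", 1:25), each = 2),
    calendar_day = as.vector(rbind(first, first + gap)), year = 2023)
  d2$rmr_ml_o2_h <- 2.5 - 0.01 * d2$calendar_day
  # exact tracking means a perfect |dRMR| ~ days fit; lm warns about it
  craw <- suppressWarnings(consistency_analysis(d2, use_day_residuals = FALSE))
  cres <- suppressWarnings(consistency_analysis(d2, use_day_residuals = TRUE))
  expect_gt(craw$beta, 0)
  expect_lt(craw$p, 1e-6)  # exact tracking: |dRMR| = 0.01 * days
  expect_equal(craw$beta, 0.01, tolerance = 1e-8)
  expect_lt(abs(cres$beta), 1e-8)

  expect_error(consistency_analysis(d2[1:4, ]), "insufficient")
})

test_that("cross-year pairs are excluded from consistency analysis", {
  d <- data.frame(
    individual_id = c("a", "a", "b", "b", "b", "c", "c", "d", "d"),
    rmr_ml_o2_h = c(1, 1.2, 0.9, 1.0, 0.8, 1.1, 1.0, 0.7, 0.9),
    calendar_day = c(150, 170, 140, 160, 150, 145, 165, 150, 175),
    year = c(2023, 2023, 2023, 2023, 2024, 2023, 2024, 2024, 2024))
  cc <- consistency_analysis(d)
  # individual b keeps its within-2023 pair; c (pure cross-year) drops
  expect_equal(cc$n, 3)
  expect_false("c" %in% cc$pairs$individual_id)
  b_row <- cc$pairs[cc$pairs$individual_id == "b", ]
  expect_equal(b_row$day_first, 140)
  expect_equal(b_row$day_last, 160)
})
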