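# Independent oracles and small builders shared across the suite.
# Oracles are deliberately naive (nested loops, direct formulas) and must
# stay independent of the package's implementation path.

# direct scalar evaluation of the flow correction
oracle_flow <- function(fr, bp, wvp) fr * (bp - wvp) / bp

# direct scalar evaluation of the oxygen-consumption equation
oracle_vo2 <- function(delta, frd, fio2 = 0.2095) {
  fe <- fio2 - delta
  frd * 60 * delta / (1 - fe)
}

# exhaustive two-stage window search: minimum-SD long window (earliest on
# ties), then minimum-mean short window inside it (earliest on ties)
oracle_window_search <- function(x, n1, n2) {
  best_sd <- Inf; i_best <- NA
  for (i in 1:(length(x) - n1 + 1)) {
    s <- sd(x[i:(i + n1 - 1)])
    if (s < best_sd) { best_sd <- s; i_best <- i }
  }
  seg <- x[i_best:(i_best + n1 - 1)]
  best_mean <- Inf; j_best <- NA
  for (j in 1:(n1 - n2 + 1)) {
    m <- mean(seg[j:(j + n2 - 1)])
    if (m < best_mean) { best_mean <- m; j_best <- j }
  }
  list(start = i_best + j_best - 1L, mean = best_mean,
       stable_start = i_best)
}

# wrap a bare VO2 vector (1 Hz) as a vo2_series
make_vo2_series <- function(x, channel = 1L, repetition = 1L, dt = 1) {
  structure(
    data.frame(time_s = (seq_along(x) - 1) * dt, vo2_ml_h = x,
               fr_d_ml_min = 100, flagged = FALSE),
    channel = channel, repetition = repetition, qc = character(0),
    dt_s = dt, class = c("vo2_series", "data.frame"))
}

# small valid trace for I/O tests
make_tiny_trace <- function(n = 10) {
  respirometry_trace(
    time_s = 0:(n - 1), o2_pct = 20.95 - 0.001 * (0:(n - 1)),
    co2_pct = rep(0.04, n), wvp_kpa = rep(1.5, n),
    bp_kpa = rep(101.3, n), fr_ml_min = rep(100, n),
    channel = rep(c(0L, 1L), length.out = n))
}
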