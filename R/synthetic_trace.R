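# Synthetic respirometry traces: inverse of the reduction chain plus
# analyzer noise, drift, channel lag and labeled activity bursts.

#' Trace simulation parameters
#'
#' Emulates an eight-chamber multiplexed push-mode system: channel 0 is the
#' empty baseline chamber, channels 1..n_animal hold animals; the
#' multiplexer dwells 15 min per channel, cycles through all channels three
#' times, and closes with another baseline dwell. Flow is ~100 ml min^-1;
#' air is rehydrated upstream so WVP is nonzero, slightly higher on animal
#' channels. Analyzer noise defaults give a VO2-equivalent white noise SD of
#' about 0.02 ml h^-1 at the default flow; O2 drift defaults to
#' -0.01 %/h (sensor drift between calibrations).
#'
#' @param fs_hz logger sampling rate (Hz); the field standard for such
#'   loggers is ~1 Hz and the value is not critical.
#' @param n_animal number of animal channels (max 7 alongside the baseline).
#' @param dwell_s multiplexer dwell per channel (s).
#' @param n_cycles number of full channel cycles.
#' @param flow_ml_min commanded flow rate.
#' @param bp_kpa barometric pressure.
#' @param wvp_kpa baseline-channel water vapor pressure.
#' @param wvp_animal_extra_kpa extra WVP on animal channels (humid chamber);
#'   also provides the switch transients used for lag estimation.
#' @param o2_baseline_pct incurrent O2 concentration (percent).
#' @param fio2_ref incurrent fractional O2 (must equal
#'   `o2_baseline_pct / 100` for a self-consistent inversion).
#' @param rq respiratory quotient used to paint the CO2 channel (QC only).
#' @param noise_o2_pct,noise_co2_pct,noise_wvp_kpa,noise_fr SD of white
#'   analyzer noise per channel, native units.
#' @param drift_o2_pct_h,drift_co2_pct_h linear drift rates (percent per
#'   hour).
#' @param lag_s injected analyzer lag of the gas channels behind WVP (s).
#' @param burst_prob probability that an animal repetition contains one
#'   activity burst.
#' @param burst_amp multiplicative VO2 amplitude of a burst (>= 1).
#' @param burst_dur_s burst duration (s).
#' @return object of class `trace_sim_params`.
#' @export
trace_sim_params <- function(fs_hz = 1, n_animal = 7, dwell_s = 900,
                             n_cycles = 3, flow_ml_min = 100,
                             bp_kpa = 101.3, wvp_kpa = 1.5,
                             wvp_animal_extra_kpa = 0.25,
                             o2_baseline_pct = 20.95, fio2_ref = 0.2095,
                             rq = 0.8,
                             noise_o2_pct = 0.00027, noise_co2_pct = 2e-04,
                             noise_wvp_kpa = 0.003, noise_fr = 0.15,
                             drift_o2_pct_h = -0.01, drift_co2_pct_h = 0.002,
                             lag_s = 0, burst_prob = 0.08, burst_amp = 3,
                             burst_dur_s = 120) {
  stopifnot(n_animal >= 1, n_animal <= 7, burst_amp >= 1,
            dwell_s > 450, lag_s >= 0)
  structure(as.list(environment()), class = "trace_sim_params")
}

# fractional O2 deficit producing a given VO2 (inverse of the VO2 equation)
delta_o2_for_vo2 <- function(vo2_ml_h, fr_d_ml_min, fio2) {
  d <- vo2_ml_h * (1 - fio2) / (60 * fr_d_ml_min - vo2_ml_h)
  if (any(d >= fio2) || any(vo2_ml_h >= 60 * fr_d_ml_min * fio2)) {
    stop("true VO2 infeasible at this flow and incurrent O2", call. = FALSE)
  }
  d
}

#' Simulate a multiplexed respirometry trace
#'
#' Builds the channel schedule, computes the O2 deflection on each animal
#' channel by inverting the VO2 equation at the (noise-free) corrected flow,
#' then layers linear drift, white analyzer noise, an injected gas-channel
#' lag, and labeled multiplicative activity bursts. Burst labels are
#' returned so activity screening can be validated against ground truth.
#'
#' @param true_vo2_ml_h vector of true resting VO2 per animal channel
#'   (length `n_animal` or shorter; ml O2 h^-1, >= 0).
#' @param params a [trace_sim_params()].
#' @param seed RNG seed; `NULL` leaves the RNG state alone (for use inside
#'   larger seeded simulations).
#' @return list: `trace` (a [respirometry_trace()]), `bursts` (data frame
#'   `channel, repetition, start_s, end_s` of injected bursts, zero rows if
#'   none), `schedule_channels` (the per-segment channel sequence).
#' @export
simulate_trace <- function(true_vo2_ml_h, params = trace_sim_params(),
                           seed = NULL) {
  stopifnot(inherits(params, "trace_sim_params"), all(true_vo2_ml_h >= 0))
  p <- params
  if (!is.null(seed)) set.seed(seed)
  n_an <- length(true_vo2_ml_h)
  stopifnot(n_an <= p$n_animal)
  seg_channels <- c(rep(c(0L, seq_len(n_an)), p$n_cycles), 0L)
  n_per_seg <- as.integer(round(p$dwell_s * p$fs_hz))
  channel <- rep(seg_channels, each = n_per_seg)
  n <- length(channel)
  dt <- 1 / p$fs_hz
  time_s <- (seq_len(n) - 1) * dt

  # per-sample true VO2 with activity bursts
  vo2 <- numeric(n)
  rep_count <- integer(n_an)
  bursts <- list()
  seg_start <- (seq_along(seg_channels) - 1L) * n_per_seg
  for (s in seq_along(seg_channels)) {
    ch <- seg_channels[s]
    if (ch == 0L) next
    rep_count[ch] <- rep_count[ch] + 1L
    idx <- seg_start[s] + seq_len(n_per_seg)
    vo2[idx] <- true_vo2_ml_h[ch]
    if (p$burst_prob > 0 && stats::runif(1) < p$burst_prob) {
      b0 <- seg_start[s] + sample.int(n_per_seg - p$burst_dur_s * p$fs_hz, 1)
      bi <- b0 + seq_len(p$burst_dur_s * p$fs_hz)
      vo2[bi] <- vo2[bi] * p$burst_amp
      bursts[[length(bursts) + 1L]] <- data.frame(
        channel = ch, repetition = rep_count[ch],
        start_s = time_s[bi[1]], end_s = time_s[bi[length(bi)]] + dt)
    }
  }

  wvp <- p$wvp_kpa + p$wvp_animal_extra_kpa * (channel > 0L)
  fr_d <- correct_flow(p$flow_ml_min, p$bp_kpa, wvp)
  delta <- delta_o2_for_vo2(vo2, fr_d, p$fio2_ref)
  drift_o2 <- p$drift_o2_pct_h * time_s / 3600
  drift_co2 <- p$drift_co2_pct_h * time_s / 3600
  o2 <- p$o2_baseline_pct + drift_o2 - 100 * delta
  co2 <- 0.04 + drift_co2 + 100 * p$rq * delta

  lag_k <- as.integer(round(p$lag_s * p$fs_hz))
  if (lag_k > 0L) {
    o2 <- c(rep(o2[1], lag_k), o2[seq_len(n - lag_k)])
    co2 <- c(rep(co2[1], lag_k), co2[seq_len(n - lag_k)])
  }

  trace <- respirometry_trace(
    time_s = time_s,
    o2_pct = o2 + stats::rnorm(n, 0, p$noise_o2_pct),
    co2_pct = pmax(0, co2 + stats::rnorm(n, 0, p$noise_co2_pct)),
    wvp_kpa = wvp + stats::rnorm(n, 0, p$noise_wvp_kpa),
    bp_kpa = rep(p$bp_kpa, n),
    fr_ml_min = p$flow_ml_min + stats::rnorm(n, 0, p$noise_fr),
    channel = channel
  )
  list(
    trace = trace,
    bursts = if (length(bursts)) do.call(rbind, bursts) else
      data.frame(channel = integer(0), repetition = integer(0),
                 start_s = numeric(0), end_s = numeric(0)),
    schedule_channels = seg_channels
  )
}

#' Noise-free trace simulation parameters
#'
#' Convenience wrapper: all noise SDs, drift rates, lag and bursts zeroed.
#'
#' @param ... overrides passed to [trace_sim_params()].
#' @return a `trace_sim_params`.
#' @export
noiseless_trace_params <- function(...) {
  quiet <- list(noise_o2_pct = 0, noise_co2_pct = 0, noise_wvp_kpa = 0,
                noise_fr = 0, drift_o2_pct_h = 0, drift_co2_pct_h = 0,
                lag_s = 0, burst_prob = 0)
  do.call(trace_sim_params, utils::modifyList(quiet, list(...)))
}
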