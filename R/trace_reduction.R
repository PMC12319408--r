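# Reduction of a raw multiplexed trace to per-repetition oxygen-consumption
# series: lag alignment, baseline drift correction, proportional conversion,
# water-vapor flow correction and the VO2 equation.

#' Reduction parameters
#'
#' @param fio2_ref incurrent fractional O2 concentration (dimensionless).
#'   Default 0.2095, atmospheric air after scrubbing; after flat-baselining,
#'   the deflection-based delta-O2 is referenced to the baseline so this value
#'   only enters the `(1 - FeO2)` denominator. Sensitivity to +/-0.002 is of
#'   order 0.3% of VO2.
#' @param lag_max_s maximum analyzer lag searched, seconds.
#' @param washout_s seconds discarded after every channel switch, before any
#'   statistic is computed (chamber air washout). 0 reproduces a literal
#'   no-trimming reduction.
#' @param baseline_mode drift interpolant across baseline-segment medians:
#'   `"linear-interp"` (default) or `"spline"` (natural cubic, needs >= 4
#'   baseline segments, otherwise falls back to linear).
#' @return object of class `reduction_params`.
#' @export
reduction_params <- function(fio2_ref = 0.2095, lag_max_s = 30,
                             washout_s = 60,
                             baseline_mode = c("linear-interp", "spline")) {
  stopifnot(fio2_ref > 0, fio2_ref < 1, lag_max_s >= 0, washout_s >= 0)
  structure(
    list(fio2_ref = fio2_ref, lag_max_s = lag_max_s, washout_s = washout_s,
         baseline_mode = match.arg(baseline_mode)),
    class = "reduction_params"
  )
}

#' Water-vapor correction of the measured flow rate
#'
#' Mass-flow meters upstream of a rehydration stage meter dry air; the flow
#' actually carrying the gas fractions at the analyzers is diluted by water
#' vapor. The corrected flow is
#' `FR_d = FR * (BP - WVP) / BP`.
#'
#' @param fr_ml_min measured flow rate (ml min^-1).
#' @param bp_kpa barometric pressure (kPa).
#' @param wvp_kpa water vapor pressure (kPa), `0 <= WVP < BP`.
#' @return corrected flow rate `FR_d` (ml min^-1), elementwise.
#' @export
correct_flow <- function(fr_ml_min, bp_kpa, wvp_kpa) {
  if (any(wvp_kpa < 0) || any(wvp_kpa >= bp_kpa)) {
    stop("require 0 <= WVP < BP", call. = FALSE)
  }
  fr_ml_min * (bp_kpa - wvp_kpa) / bp_kpa
}

#' Oxygen consumption from the O2 deficit
#'
#' For an excurrent stream scrubbed of water and CO2 before O2 analysis,
#' `VO2 = 60 * FR_d * dO2 / (1 - FeO2)` with `FeO2 = FiO2 - dO2`, where
#' `dO2` is the incurrent-minus-excurrent fractional O2 difference. The
#' factor 60 converts the ml min^-1 flow to an hourly rate, so VO2 is in
#' ml O2 h^-1.
#'
#' @param delta_o2 fractional O2 deficit (dimensionless, `0 <= dO2 < FiO2`).
#' @param fr_d_ml_min corrected flow rate (ml min^-1).
#' @param params a [reduction_params()] supplying `fio2_ref`.
#' @return VO2 in ml O2 h^-1, elementwise.
#' @export
compute_vo2 <- function(delta_o2, fr_d_ml_min, params = reduction_params()) {
  if (any(delta_o2 >= params$fio2_ref)) {
    stop("delta_o2 must be below the incurrent fraction fio2_ref",
         call. = FALSE)
  }
  fe_o2 <- params$fio2_ref - delta_o2
  (fr_d_ml_min * 60) * delta_o2 / (1 - fe_o2)
}

# Cross-correlation lag of a gas channel against the WVP channel, both
# differenced and rectified so only the switch transients carry weight.
estimate_lag <- function(gas, wvp, lag_max) {
  x <- abs(diff(wvp))
  y <- abs(diff(gas))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(lag = 0L, flag = "flat"))
  }
  n <- length(x)
  score <- vapply(0:lag_max, function(k) {
    xs <- x[seq_len(n - k)]
    ys <- y[seq_len(n - k) + k]
    sum(xs * ys) / sqrt(sum(xs^2) * sum(ys^2))
  }, numeric(1))
  k <- which.max(score) - 1L
  # a true lag beyond the search bound leaves all candidate alignments
  # poor: the transient spike trains never overlap
  if (score[k + 1L] < 0.3) {
    return(list(lag = 0L, flag = "lag_at_bound"))
  }
  list(lag = k, flag = "ok")
}

#' Align gas analyzer channels with the water-vapor channel
#'
#' In a serial analyzer chain the O2 and CO2 cells sit downstream of the WVP
#' cell, so their response to a channel switch arrives later. The integer-
#' sample lag of each gas channel is estimated by maximizing the cross-
#' correlation of the rectified first differences (which concentrate at
#' switch transients) against the WVP channel, then removed by shifting the
#' gas channel earlier (tail padded with its last value). A channel with no
#' transients has an undeterminable lag and is returned unshifted with a
#' warning flag, as is a lag that saturates the search bound `lag_max_s`.
#'
#' @param trace a [respirometry_trace()].
#' @param params a [reduction_params()].
#' @return the trace with shifted gas channels; attribute `lag` is a list
#'   with per-channel `lag` (samples) and `flag` (`"ok"`, `"flat"`,
#'   `"lag_at_bound"`).
#' @export
correct_lag <- function(trace, params = reduction_params()) {
  stopifnot(inherits(trace, "respirometry_trace"))
  dt <- attr(trace, "dt_s")
  lag_max <- as.integer(floor(params$lag_max_s / dt))
  out <- trace
  info <- list()
  for (ch in c("o2_pct", "co2_pct")) {
    est <- estimate_lag(trace[[ch]], trace$wvp_kpa, lag_max)
    info[[ch]] <- est
    k <- est$lag
    if (k > 0L) {
      n <- nrow(trace)
      out[[ch]] <- c(trace[[ch]][(k + 1L):n], rep(trace[[ch]][n], k))
    }
  }
  attr(out, "lag") <- info
  attr(out, "dt_s") <- dt
  class(out) <- class(trace)
  out
}

# Per-baseline-segment median of a channel, washout removed; segment
# midpoint used as the node time for the drift interpolant.
baseline_nodes <- function(trace, schedule, channel, washout_s) {
  base <- schedule[schedule$channel == 0L & !schedule$short, , drop = FALSE]
  if (nrow(base) < 2L) {
    stop("need >= 2 baseline (channel 0) segments for drift correction",
         call. = FALSE)
  }
  t <- trace$time_s
  nodes <- lapply(seq_len(nrow(base)), function(i) {
    keep <- t >= base$start_s[i] + washout_s & t < base$end_s[i]
    if (!any(keep)) keep <- t >= base$start_s[i] & t < base$end_s[i]
    c(time = mean(t[keep]), value = stats::median(trace[[channel]][keep]))
  })
  do.call(rbind, nodes)
}

drift_curve <- function(nodes, t_out, mode) {
  if (mode == "spline" && nrow(nodes) >= 4L) {
    stats::spline(nodes[, "time"], nodes[, "value"], xout = t_out,
                  method = "natural")$y
  } else {
    stats::approx(nodes[, "time"], nodes[, "value"], xout = t_out,
                  rule = 2)$y
  }
}

#' Baseline drift correction and proportional gas conversion
#'
#' Fits a drift curve through the per-baseline-segment medians of each gas
#' channel and references the signal to it, yielding a flat baseline. The O2
#' deflection is negated and divided by 100 (O2 dips below baseline when an
#' animal consumes it, so `delta_o2 >= 0` during consumption); CO2 is
#' divided by 100 with the native sign (excess above baseline positive).
#'
#' @param trace a (lag-corrected) [respirometry_trace()].
#' @param schedule its [infer_schedule()] result.
#' @param params a [reduction_params()].
#' @return data frame `time_s, delta_o2, delta_co2, extrapolated` with one
#'   row per trace sample; `extrapolated` marks samples outside the time span
#'   of the baseline nodes (animal segment not bracketed by baselines).
#' @export
baseline_correct <- function(trace, schedule, params = reduction_params()) {
  stopifnot(inherits(trace, "respirometry_trace"))
  t <- trace$time_s
  no2 <- baseline_nodes(trace, schedule, "o2_pct", params$washout_s)
  nco2 <- baseline_nodes(trace, schedule, "co2_pct", params$washout_s)
  drift_o2 <- drift_curve(no2, t, params$baseline_mode)
  drift_co2 <- drift_curve(nco2, t, params$baseline_mode)
  data.frame(
    time_s = t,
    delta_o2 = (drift_o2 - trace$o2_pct) / 100,
    delta_co2 = (trace$co2_pct - drift_co2) / 100,
    extrapolated = t < min(no2[, "time"]) | t > max(no2[, "time"])
  )
}

#' Reduce one trial to per-repetition VO2 series
#'
#' Applies the full reduction chain: [correct_lag()], [baseline_correct()],
#' [correct_flow()], [compute_vo2()]; drops `washout_s` seconds after every
#' channel switch; and returns one `vo2_series` per animal repetition with QC
#' provenance (lag flags, drift extrapolation, negative-deficit samples).
#'
#' @param trace a [respirometry_trace()].
#' @param schedule optional [infer_schedule()] result (inferred if omitted).
#' @param params a [reduction_params()].
#' @return list of `vo2_series` objects, each a data frame
#'   `time_s, vo2_ml_h, fr_d_ml_min, flagged` with attributes `channel`,
#'   `repetition`, `qc` (character vector of trial-level flags).
#' @export
reduce_trial <- function(trace, schedule = NULL, params = reduction_params()) {
  stopifnot(inherits(trace, "respirometry_trace"))
  if (is.null(schedule)) schedule <- infer_schedule(trace)
  aligned <- correct_lag(trace, params)
  lag_info <- attr(aligned, "lag")
  deltas <- baseline_correct(aligned, schedule, params)
  fr_d <- correct_flow(aligned$fr_ml_min, aligned$bp_kpa, aligned$wvp_kpa)
  vo2 <- compute_vo2(pmin(deltas$delta_o2, params$fio2_ref - 1e-9), fr_d,
                     params)
  animal <- schedule[schedule$channel > 0L & !schedule$short, , drop = FALSE]
  t <- aligned$time_s
  out <- lapply(seq_len(nrow(animal)), function(i) {
    keep <- t >= animal$start_s[i] + params$washout_s & t < animal$end_s[i]
    qc <- character(0)
    for (ch in names(lag_info)) {
      if (lag_info[[ch]]$flag != "ok") {
        qc <- c(qc, paste0(ch, ":", lag_info[[ch]]$flag))
      }
    }
    if (any(deltas$extrapolated[keep])) qc <- c(qc, "baseline_extrapolated")
    s <- data.frame(
      time_s = t[keep],
      vo2_ml_h = vo2[keep],
      fr_d_ml_min = fr_d[keep],
      flagged = deltas$extrapolated[keep] | deltas$delta_o2[keep] < 0
    )
    structure(s, channel = animal$channel[i],
              repetition = animal$repetition[i], qc = qc,
              dt_s = attr(trace, "dt_s"),
              class = c("vo2_series", "data.frame"))
  })
  names(out) <- sprintf("ch%d_rep%d", animal$channel, animal$repetition)
  out
}

#' @export
print.vo2_series <- function(x, ...) {
  cat(sprintf(
    "vo2_series: channel %d repetition %d, %d samples, mean VO2 %.3f ml/h\n",
    attr(x, "channel"), attr(x, "repetition"), nrow(x), mean(x$vo2_ml_h)))
  invisible(x)
}
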