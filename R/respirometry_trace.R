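# Domain types and file I/O for raw respirometry traces, channel schedules
# and individual metadata.

#' Construct a respirometry trace
#'
#' A `respirometry_trace` is the raw, synchronized multi-channel time series
#' logged by a multiplexed push-mode flow-through respirometry system: oxygen
#' and carbon dioxide concentrations of the analyzed (excurrent) air stream,
#' water vapor pressure, barometric pressure, mass-flow rate, and the id of
#' the chamber currently routed to the analyzers. Channel 0 is by convention
#' the empty baseline (control) chamber used to define incurrent gas levels
#' and analyzer drift.
#'
#' @param time_s numeric, seconds from recording start; strictly increasing
#'   with a constant step.
#' @param o2_pct O2 concentration of the analyzed stream (percent, in (0,100)).
#' @param co2_pct CO2 concentration (percent).
#' @param wvp_kpa water vapor pressure (kPa); must satisfy
#'   `0 <= wvp_kpa < bp_kpa`.
#' @param bp_kpa barometric pressure (kPa).
#' @param fr_ml_min measured flow rate (ml min^-1), positive.
#' @param channel integer chamber id per sample; 0 = baseline chamber.
#' @return A data frame of class `respirometry_trace` with attribute `dt_s`,
#'   the sampling interval in seconds.
#' @export
respirometry_trace <- function(time_s, o2_pct, co2_pct, wvp_kpa, bp_kpa,
                               fr_ml_min, channel) {
  x <- data.frame(
    time_s = as.numeric(time_s),
    o2_pct = as.numeric(o2_pct),
    co2_pct = as.numeric(co2_pct),
    wvp_kpa = as.numeric(wvp_kpa),
    bp_kpa = as.numeric(bp_kpa),
    fr_ml_min = as.numeric(fr_ml_min),
    channel = as.integer(channel)
  )
  validate_trace(x)
}

validate_trace <- function(x) {
  num <- setdiff(trace_columns, "channel")
  x[num] <- lapply(x[num], as.numeric)
  x$channel <- as.integer(x$channel)
  n <- nrow(x)
  if (n < 2L) stop("trace must contain at least two samples", call. = FALSE)
  dt <- diff(x$time_s)
  if (any(dt <= 0)) {
    stop("trace time must be strictly increasing", call. = FALSE)
  }
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop("trace must be uniformly sampled (constant time step)", call. = FALSE)
  }
  if (any(x$fr_ml_min <= 0)) stop("flow rate must be positive", call. = FALSE)
  if (any(x$wvp_kpa < 0) || any(x$wvp_kpa >= x$bp_kpa)) {
    stop("water vapor pressure must satisfy 0 <= WVP < BP", call. = FALSE)
  }
  if (any(x$o2_pct <= 0) || any(x$o2_pct >= 100)) {
    stop("O2 concentration must lie in (0, 100) percent", call. = FALSE)
  }
  attr(x, "dt_s") <- stats::median(dt)
  class(x) <- c("respirometry_trace", "data.frame")
  x
}

#' @export
print.respirometry_trace <- function(x, ...) {
  dt <- attr(x, "dt_s")
  cat(sprintf(
    "respirometry_trace: %d samples @ %.6g s, %.1f min, channels {%s}\n",
    nrow(x), dt, diff(range(x$time_s)) / 60,
    paste(sort(unique(x$channel)), collapse = ",")
  ))
  invisible(x)
}

trace_columns <- c("time_s", "o2_pct", "co2_pct", "wvp_kpa", "bp_kpa",
                   "fr_ml_min", "channel")

#' Read a respirometry trace from CSV
#'
#' The native dialect is a long-form CSV with header
#' `time_s,o2_pct,co2_pct,wvp_kpa,bp_kpa,fr_ml_min,channel` (UTF-8, `.`
#' decimal). Loggers exporting other column names are supported through
#' `dialect`, a named character vector mapping native names to the exported
#' ones, e.g. `c(o2_pct = "O2", channel = "MUX")`.
#'
#' @param path path to a CSV file.
#' @param dialect optional named character vector remapping column names.
#' @return a validated [respirometry_trace()].
#' @export
read_trace <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE)
  wanted <- stats::setNames(trace_columns, trace_columns)
  if (!is.null(dialect)) wanted[names(dialect)] <- dialect
  missing <- wanted[!wanted %in% names(raw)]
  if (length(missing)) {
    stop("trace file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_trace(stats::setNames(raw[, wanted, drop = FALSE], trace_columns))
}

#' Write a respirometry trace to CSV in the native dialect
#'
#' `read_trace(write_trace(x, f))` reproduces `x` exactly: values are written
#' with full double precision (17 significant digits).
#'
#' @param trace a [respirometry_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "respirometry_trace"))
  df <- as.data.frame(trace)[, trace_columns]
  num <- setdiff(trace_columns, "channel")
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Recover the channel-switch schedule from a trace
#'
#' Run-length encodes the active-channel marker into contiguous,
#' non-overlapping segments and assigns each animal chamber (channel > 0) a
#' repetition index 1..3 in temporal order. Multiplexed protocols record each
#' animal chamber at most three times per trial; a fourth occurrence is a
#' schedule error. Segments shorter than `min_dwell_s` (e.g. a glitching
#' marker) are flagged `short` and ignored downstream.
#'
#' @param trace a [respirometry_trace()].
#' @param min_dwell_s minimum credible segment duration in seconds.
#' @return A data frame of class `channel_schedule` with columns `channel`,
#'   `start_s`, `end_s` (half-open, end exclusive), `n_samples`, `repetition`
#'   (NA for baseline), and `short`.
#' @export
infer_schedule <- function(trace, min_dwell_s = 120) {
  stopifnot(inherits(trace, "respirometry_trace"))
  dt <- attr(trace, "dt_s")
  r <- rle(trace$channel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(
    channel = r$values,
    start_s = trace$time_s[starts],
    end_s = trace$time_s[ends] + dt,
    n_samples = r$lengths
  )
  seg$short <- seg$n_samples * dt < min_dwell_s
  seg$repetition <- NA_integer_
  for (ch in unique(seg$channel[seg$channel > 0L])) {
    idx <- which(seg$channel == ch & !seg$short)
    if (length(idx) > 3L) {
      stop(sprintf("channel %d appears %d times; at most 3 repetitions allowed",
                   ch, length(idx)), call. = FALSE)
    }
    seg$repetition[idx] <- seq_along(idx)
  }
  class(seg) <- c("channel_schedule", "data.frame")
  seg
}

#' Read individual metadata
#'
#' Expects columns `individual_id,mass_g,date,year,temp_c,pond`. `date` is
#' ISO `YYYY-MM-DD`; a `calendar_day` column (ISO day-of-year) is derived.
#' Skin temperature is checked against the plausible field range of 10-35
#' degrees C for a calling ectotherm.
#'
#' @param path CSV path.
#' @return data frame with an added `calendar_day` column, `year` as factor
#'   with reference level 2023.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  md <- utils::read.csv(path)
  need <- c("individual_id", "mass_g", "date", "year", "temp_c", "pond")
  missing <- setdiff(need, names(md))
  if (length(missing)) {
    stop("metadata missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(md$mass_g <= 0)) stop("mass_g must be positive", call. = FALSE)
  if (any(md$temp_c < 10 | md$temp_c > 35)) {
    stop("temp_c outside plausible range [10, 35] degrees C", call. = FALSE)
  }
  md$calendar_day <- as.integer(strftime(as.Date(md$date), "%j"))
  if (any(is.na(md$calendar_day))) stop("unparseable date(s)", call. = FALSE)
  md$year <- factor(md$year, levels = sort(unique(c(2023, md$year))))
  md
}
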