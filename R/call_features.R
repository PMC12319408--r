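# The five advertisement-call characteristics from call event tables, and
# inter-observer reliability.

#' Per-call rate series
#'
#' The call-by-call rate is the reciprocal of the onset-to-onset interval
#' between consecutive calls; the final call of a recording has no following
#' onset and therefore no rate.
#'
#' @param onset_s strictly increasing call onset times (s), length >= 2.
#' @return numeric of length `length(onset_s)`; the last element is `NA`.
#' @export
call_rate <- function(onset_s) {
  if (length(onset_s) < 2L) stop("need at least two calls", call. = FALSE)
  gaps <- diff(onset_s)
  if (any(gaps <= 0)) stop("call onsets must be strictly increasing",
                           call. = FALSE)
  c(1 / gaps, NA_real_)
}

#' Per-call effort
#'
#' Call effort is the call duration multiplied by the call rate, a
#' dimensionless fraction of time spent calling. Undefined (NA) wherever the
#' rate is undefined (the final call), and excluded from recording means.
#'
#' @param duration_s per-call durations (s).
#' @param rate_per_s per-call rates from [call_rate()].
#' @return per-call effort, same length.
#' @export
call_effort <- function(duration_s, rate_per_s) {
  stopifnot(length(duration_s) == length(rate_per_s))
  duration_s * rate_per_s
}

validate_call_events <- function(events) {
  need <- c("recording_id", "call_idx", "onset_s", "offset_s", "pulse_count",
            "domfreq_hz")
  missing <- setdiff(need, names(events))
  if (length(missing)) {
    stop("call events missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(events$offset_s <= events$onset_s)) {
    stop("call offsets must follow onsets", call. = FALSE)
  }
  if (any(events$pulse_count < 1)) stop("pulse_count must be >= 1",
                                        call. = FALSE)
  events
}

#' Read a call event table
#'
#' Columns: `recording_id,call_idx,onset_s,offset_s,pulse_count,domfreq_hz`
#' and optionally `observer`.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_call_events <- function(path) {
  if (!file.exists(path)) stop("call event file not found: ", path,
                               call. = FALSE)
  validate_call_events(utils::read.csv(path))
}

#' Per-recording means of the five call characteristics
#'
#' Computes, per recording, the mean call duration, pulse number, dominant
#' frequency, call rate and call effort, each averaged over the calls for
#' which it is defined (rate and effort exclude the final call). Events are
#' sorted by onset within recording first, so the result is invariant to row
#' order.
#'
#' @param events a call event table (see [read_call_events()]).
#' @return data frame, one row per recording:
#'   `recording_id, n_calls, duration_s, pulse_number, domfreq_hz,
#'    call_rate, call_effort`.
#' @export
recording_features <- function(events) {
  events <- validate_call_events(as.data.frame(events))
  out <- lapply(split(events, events$recording_id), function(e) {
    e <- e[order(e$onset_s), ]
    if (any(duplicated(e$onset_s))) {
      stop("duplicate call onsets in recording ", e$recording_id[1],
           call. = FALSE)
    }
    dur <- e$offset_s - e$onset_s
    rate <- if (nrow(e) >= 2L) call_rate(e$onset_s) else NA_real_
    eff <- call_effort(dur, rate)
    data.frame(
      recording_id = e$recording_id[1],
      n_calls = nrow(e),
      duration_s = mean(dur),
      pulse_number = mean(e$pulse_count),
      domfreq_hz = mean(e$domfreq_hz),
      call_rate = mean(rate, na.rm = TRUE),
      call_effort = mean(eff, na.rm = TRUE)
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Inter-observer reliability of a call measurement
#'
#' For matched per-call measurements by two observers: the Pearson
#' correlation and the ordinary-least-squares slope of observer B on
#' observer A. A slope close to 1 together with high r indicates the two
#' observers measure the same quantity on the same scale.
#'
#' @param a,b equal-length matched measurement vectors, `n >= 3`.
#' @return list `r` (correlation), `slope` (OLS slope of `b ~ a`), `n`.
#' @export
interobserver_reliability <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("need >= 3 matched measurements", call. = FALSE)
  if (stats::var(a) == 0) stop("observer A has zero variance; slope undefined",
                               call. = FALSE)
  list(r = stats::cor(a, b),
       slope = unname(stats::cov(a, b) / stats::var(a)),
       n = length(a))
}
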