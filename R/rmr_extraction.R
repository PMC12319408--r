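# Screening of repetitions for activity and extraction of a trial's resting
# metabolic rate by a two-stage stable-window search.

#' Window-search parameters
#'
#' The trial RMR is the lowest 60-s mean VO2 found inside the most stable
#' (minimum SD) 450-s interval of each usable repetition, minimized across
#' repetitions. Both window lengths are in seconds and converted to samples
#' internally.
#'
#' @param stable_window_s length of the stage-1 minimum-SD window (s).
#' @param min_window_s length of the stage-2 minimum-mean window (s).
#' @param stride_s window stride; default one sample.
#' @param activity_jump_threshold reject a repetition when the maximum
#'   absolute first difference of the smoothed VO2 series exceeds this
#'   multiple of the MAD of those differences ("sudden changes" = activity).
#'   Default 6, calibrated on generator activity bursts; `Inf` disables.
#' @param smooth_s smoothing window for the jump statistic (s).
#' @param max_flagged_frac discard a repetition when more than this fraction
#'   of its samples carries a reduction QC flag.
#' @return object of class `window_search_params`.
#' @export
window_search_params <- function(stable_window_s = 450, min_window_s = 60,
                                 stride_s = NULL,
                                 activity_jump_threshold = 6,
                                 smooth_s = 11, max_flagged_frac = 0.2) {
  stopifnot(min_window_s <= stable_window_s, activity_jump_threshold > 0)
  structure(
    list(stable_window_s = stable_window_s, min_window_s = min_window_s,
         stride_s = stride_s, activity_jump_threshold = activity_jump_threshold,
         smooth_s = smooth_s, max_flagged_frac = max_flagged_frac),
    class = "window_search_params"
  )
}

# centered moving average with shrinking windows at the edges (no NA
# padding: edge discontinuities would masquerade as activity jumps)
running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  h <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Screen a repetition for activity
#'
#' Automated stand-in for visual smoothness inspection: the VO2 series is
#' smoothed, and the repetition is discarded when the largest absolute
#' first difference exceeds `activity_jump_threshold` times the MAD of the
#' differences, or when too many samples carry reduction QC flags. A series
#' whose differences have zero MAD (flat) is kept unless it contains any
#' strictly positive jump, which is then infinitely many MADs away.
#'
#' @param rep a `vo2_series` from [reduce_trial()].
#' @param params a [window_search_params()].
#' @return list `keep` (logical), `reason` (`"ok"`, `"activity_jump"`,
#'   `"qc_flags"`), `statistic` (jump size in MAD units).
#' @export
screen_activity <- function(rep, params = window_search_params()) {
  stopifnot(nrow(rep) > 0L)
  dt <- attr(rep, "dt_s") %||% 1
  w <- max(1L, round(params$smooth_s / dt))
  sm <- running_mean(rep$vo2_ml_h, w)
  d <- diff(sm)
  m <- stats::mad(d)  # consistency-scaled: ~SD under Gaussian noise
  eps <- 1e-8 * max(1, abs(stats::median(rep$vo2_ml_h)))
  stat <- if (m > eps) max(abs(d)) / m else if (max(abs(d)) > eps) Inf else 0
  if (is.finite(params$activity_jump_threshold) &&
      stat > params$activity_jump_threshold) {
    return(list(keep = FALSE, reason = "activity_jump", statistic = stat))
  }
  if (mean(rep$flagged) > params$max_flagged_frac) {
    return(list(keep = FALSE, reason = "qc_flags", statistic = stat))
  }
  list(keep = TRUE, reason = "ok", statistic = stat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Find a repetition's candidate RMR window
#'
#' Stage 1 slides a `stable_window_s` window across the repetition and keeps
#' the one with the lowest VO2 standard deviation; stage 2 slides a
#' `min_window_s` window inside it and keeps the one with the lowest mean.
#' Ties are broken by the earliest start time at both stages.
#'
#' @param rep a `vo2_series`.
#' @param params a [window_search_params()].
#' @return list `window` (`c(start_s, end_s)`, half-open), `mean_vo2`,
#'   `stable_window` (`c(start_s, end_s)` of the stage-1 interval), or `NULL`
#'   with a warning attribute if the repetition is shorter than
#'   `stable_window_s`.
#' @export
find_candidate <- function(rep, params = window_search_params()) {
  dt <- attr(rep, "dt_s") %||% 1
  x <- rep$vo2_ml_h
  n <- length(x)
  n1 <- round(params$stable_window_s / dt)
  n2 <- round(params$min_window_s / dt)
  stride <- max(1L, round((params$stride_s %||% dt) / dt))
  if (n < n1) return(NULL)
  starts1 <- seq.int(1L, n - n1 + 1L, by = stride)
  sds <- vapply(starts1, function(i) stats::sd(x[i:(i + n1 - 1L)]), numeric(1))
  i1 <- starts1[which.min(sds)]
  seg <- x[i1:(i1 + n1 - 1L)]
  starts2 <- seq.int(1L, n1 - n2 + 1L, by = stride)
  means <- vapply(starts2, function(j) mean(seg[j:(j + n2 - 1L)]), numeric(1))
  j <- starts2[which.min(means)]
  start <- rep$time_s[i1 + j - 1L]
  list(
    window = c(start, start + n2 * dt),
    mean_vo2 = means[which.min(means)],
    stable_window = c(rep$time_s[i1], rep$time_s[i1] + n1 * dt)
  )
}

#' Extract a trial's RMR
#'
#' Screens each repetition with [screen_activity()], runs [find_candidate()]
#' on the survivors, and takes the minimum candidate mean as the trial RMR.
#' A trial with no usable repetition is returned with `usable = FALSE`
#' (mirrors removal of whole trials with technical issues or activity).
#'
#' @param reps list of `vo2_series` (one trial's repetitions for one
#'   individual).
#' @param params a [window_search_params()].
#' @param individual_id,date optional provenance carried into the result.
#' @return object of class `trial_rmr`: list with `rmr_ml_o2_h`, `repetition`
#'   (winning repetition index), `channel`, `window`, `n_reps_used`,
#'   `n_discarded`, `usable`, `individual_id`, `date`, `screen` (per-rep
#'   decisions).
#' @export
extract_trial_rmr <- function(reps, params = window_search_params(),
                              individual_id = NA, date = NA) {
  stopifnot(length(reps) >= 1L)
  screen <- lapply(reps, screen_activity, params = params)
  keep <- vapply(screen, `[[`, logical(1), "keep")
  cand <- vector("list", length(reps))
  for (i in which(keep)) cand[[i]] <- find_candidate(reps[[i]], params)
  ok <- keep & !vapply(cand, is.null, logical(1))
  res <- list(
    individual_id = individual_id, date = date,
    rmr_ml_o2_h = NA_real_, repetition = NA_integer_, channel = NA_integer_,
    window = c(NA_real_, NA_real_),
    n_reps_used = sum(ok), n_discarded = sum(!ok),
    usable = any(ok), screen = screen
  )
  if (any(ok)) {
    means <- vapply(which(ok), function(i) cand[[i]]$mean_vo2, numeric(1))
    w <- which(ok)[which.min(means)]
    res$rmr_ml_o2_h <- cand[[w]]$mean_vo2
    res$repetition <- attr(reps[[w]], "repetition") %||% w
    res$channel <- attr(reps[[w]], "channel") %||% NA_integer_
    res$window <- cand[[w]]$window
  }
  structure(res, class = "trial_rmr")
}

#' @export
print.trial_rmr <- function(x, ...) {
  if (x$usable) {
    cat(sprintf(
      "trial_rmr: %.4f ml O2/h (rep %d, window [%g, %g) s, %d/%d reps used)\n",
      x$rmr_ml_o2_h, x$repetition, x$window[1], x$window[2],
      x$n_reps_used, x$n_reps_used + x$n_discarded))
  } else {
    cat("trial_rmr: unusable (all repetitions discarded)\n")
  }
  invisible(x)
}
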