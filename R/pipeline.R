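# Configuration, orchestration and CLI: ties simulate -> reduce -> rmr ->
# calls -> analyze into one reproducible, manifest-tracked run.

#' Build a run configuration
#'
#' A run configuration is a plain named list (round-trippable through YAML)
#' holding the seed, output directory, scale of the simulated cohort and
#' per-stage parameter overrides. `read_run_config()` /
#' `write_run_config()` (de)serialize it losslessly.
#'
#' @param seed integer seed used for every stochastic stage (mandatory).
#' @param out_dir output directory.
#' @param cohort,trace,calls named lists of overrides for
#'   [cohort_params()], [trace_sim_params()], [call_sim_params()].
#' @param reduction,window overrides for [reduction_params()],
#'   [window_search_params()].
#' @param n_boot bootstrap replicates for the repeatability stage.
#' @param use_traces if `TRUE` (default) measured RMR comes from the full
#'   trace simulation + reduction + window search; if `FALSE` the latent
#'   trial RMR is used directly (fast, for statistics-only runs).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(seed, out_dir = "anuranRMR_run", cohort = list(),
                       trace = list(), calls = list(), reduction = list(),
                       window = list(), n_boot = 1000, use_traces = TRUE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 cohort = cohort, trace = trace, calls = calls,
                 reduction = reduction, window = window,
                 n_boot = n_boot, use_traces = use_traces),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

apply_overrides <- function(constructor, overrides) {
  do.call(constructor, overrides)
}

#' Group cohort trials into respirometer runs and simulate their traces
#'
#' Trials sharing a measurement day (calendar day x year) are measured in
#' the same multiplexed run, up to `n_animal` chambers per run; busier days
#' spill into additional runs. Each run's trace is simulated with the
#' trials' latent RMR as the chamber-wise true VO2.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param trace_params a [trace_sim_params()].
#' @param seed RNG seed.
#' @return list of runs; each has `trace`, `bursts`, and `trial_rows`
#'   (row indices into `cohort$trials`, ordered by channel 1..k).
#' @export
simulate_trial_traces <- function(cohort, trace_params = trace_sim_params(),
                                  seed = 1) {
  set.seed(seed)
  trials <- cohort$trials
  key <- paste(trials$year, trials$calendar_day)
  runs <- list()
  for (day in unique(key)) {
    rows <- which(key == day)
    for (chunk in split(rows, ceiling(seq_along(rows) /
                                        trace_params$n_animal))) {
      sim <- simulate_trace(trials$true_rmr[chunk], trace_params)
      runs[[length(runs) + 1L]] <- list(trace = sim$trace,
                                        bursts = sim$bursts,
                                        trial_rows = chunk)
    }
  }
  runs
}

#' Extract measured RMR for every trial in a set of simulated runs
#'
#' Reduces each run's trace, groups the repetition series by chamber, and
#' applies the activity screen and two-stage window search.
#'
#' @param runs output of [simulate_trial_traces()].
#' @param cohort the cohort the runs were built from.
#' @param reduction a [reduction_params()].
#' @param window a [window_search_params()].
#' @return `cohort$trials` with added columns `rmr_ml_o2_h` (measured; NA if
#'   the trial was unusable), `n_reps_used`, `usable`.
#' @export
extract_cohort_rmr <- function(runs, cohort,
                               reduction = reduction_params(),
                               window = window_search_params()) {
  trials <- cohort$trials
  trials$rmr_ml_o2_h <- NA_real_
  trials$n_reps_used <- 0L
  trials$usable <- FALSE
  for (run in runs) {
    schedule <- infer_schedule(run$trace)
    series <- reduce_trial(run$trace, schedule, reduction)
    chans <- vapply(series, attr, integer(1), "channel")
    for (j in seq_along(run$trial_rows)) {
      reps <- series[chans == j]
      if (!length(reps)) next
      tr <- extract_trial_rmr(reps, window)
      row <- run$trial_rows[j]
      trials$rmr_ml_o2_h[row] <- tr$rmr_ml_o2_h
      trials$n_reps_used[row] <- tr$n_reps_used
      trials$usable[row] <- tr$usable
    }
  }
  trials
}

#' Run the full pipeline
#'
#' Simulate a cohort, measure every trial through the respirometry path
#' (unless `use_traces = FALSE`), simulate and summarize call recordings,
#' fit the call-trait and RMR mixed models, estimate adjusted repeatability
#' and the consistency regressions, and write all stage outputs plus a
#' manifest (package version, config hash, output checksums) to
#' `config$out_dir`. Deterministic: identical config (including seed)
#' yields identical output checksums. On error the failing stage is named
#' and an `INCOMPLETE` marker is left in the output directory.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `trials`, `features`, `call_models`,
#'   `rmr_model`, `repeatability`, `consistency_raw`, `consistency_resid`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(config$out_dir, "INCOMPLETE")
  file.create(marker)
  stage <- "setup"
  result <- tryCatch({
    stage <- "simulate"
    cp <- apply_overrides(cohort_params,
                          c(config$cohort, list(seed = config$seed)))
    cohort <- simulate_cohort(cp)

    stage <- "reduce+rmr"
    if (isTRUE(config$use_traces)) {
      tp <- apply_overrides(trace_sim_params, config$trace)
      runs <- simulate_trial_traces(cohort, tp, seed = config$seed + 1L)
      trials <- extract_cohort_rmr(
        runs, cohort,
        apply_overrides(reduction_params, config$reduction),
        apply_overrides(window_search_params, config$window))
      trials <- trials[trials$usable & !is.na(trials$rmr_ml_o2_h), ]
    } else {
      trials <- cohort$trials
      trials$rmr_ml_o2_h <- trials$true_rmr
    }

    stage <- "calls"
    clp <- apply_overrides(call_sim_params, config$calls)
    calls <- simulate_calls(cohort, clp, seed = config$seed + 2L)
    features <- recording_features(calls$events)
    features <- merge(calls$recordings[, c("recording_id", "individual_id",
                                           "trial", "calendar_day", "year",
                                           "mass_g", "temp_c")],
                      features, by = "recording_id")
    features <- merge(features,
                      trials[, c("individual_id", "trial", "rmr_ml_o2_h")],
                      by = c("individual_id", "trial"))

    stage <- "analyze"
    call_models <- fit_call_models(features)
    rmr_model <- fit_rmr_model(trials, "linear")
    rpt <- repeatability(trials, "rmr_ml_o2_h", c("mass_g", "calendar_day"),
                         n_boot = config$n_boot, seed = config$seed + 3L)
    cons_raw <- consistency_analysis(trials, use_day_residuals = FALSE)
    cons_res <- consistency_analysis(trials, use_day_residuals = TRUE)

    stage <- "write"
    out <- config$out_dir
    utils::write.csv(trials, file.path(out, "trials.csv"), row.names = FALSE)
    utils::write.csv(features, file.path(out, "call_features.csv"),
                     row.names = FALSE)
    utils::write.csv(call_model_table(call_models),
                     file.path(out, "table_call_models.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(response = "rmr_ml_o2_h",
                           rmr_model$coefficients),
                     file.path(out, "table_rmr_model.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(R = rpt$R, ci = c(rpt$ci_lower, rpt$ci_upper), p = rpt$p_lrt,
           n_boot = rpt$n_boot, n_obs = rpt$n_obs,
           n_groups = rpt$n_groups),
      file.path(out, "repeatability.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(raw = unclass(cons_raw)[c("beta", "t", "p", "n")],
           day_residualized = unclass(cons_res)[c("beta", "t", "p", "n")]),
      file.path(out, "consistency.json"), auto_unbox = TRUE, digits = NA)

    stage <- "manifest"
    outputs <- c("trials.csv", "call_features.csv", "table_call_models.csv",
                 "table_rmr_model.csv", "repeatability.json",
                 "consistency.json")
    manifest <- list(
      package = "anuranRMR",
      version = as.character(utils::packageVersion("anuranRMR")),
      config_hash = digest::digest(unclass(config)),
      seed = config$seed,
      checksums = stats::setNames(
        vapply(file.path(out, outputs), digest::digest, character(1),
               file = TRUE), outputs)
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    file.remove(marker)
    invisible(list(trials = trials, features = features,
                   call_models = call_models, rmr_model = rmr_model,
                   repeatability = rpt, consistency_raw = cons_raw,
                   consistency_resid = cons_res, manifest = manifest))
  }, error = function(e) {
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

call_model_table <- function(models) {
  do.call(rbind, lapply(names(models), function(nm) {
    cbind(response = nm, models[[nm]]$coefficients)
  }))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort + call events),
#' `reduce` (trace CSV to per-repetition VO2 CSV), `rmr` (reduced VO2 CSV
#' to per-trial RMR CSV), `calls` (event CSV to recording features CSV),
#' `analyze` (trial + feature CSVs to model tables / reports), `run`
#' (full pipeline from a YAML config). See `inst/cli/anuranRMR` for the
#' executable wrapper.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 ok), invisibly.
#' @export
rmr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: anuranRMR <simulate|reduce|rmr|calls|analyze|run> [options]",
    "  simulate --seed S --out DIR [--n N]",
    "  reduce   --trace F.csv --out F_vo2.csv [--washout S]",
    "  rmr      --vo2 F_vo2.csv --out F_rmr.csv",
    "  calls    --events F.csv --out F_features.csv",
    "  analyze  --trials F.csv [--features G.csv] --out DIR [--nboot B] [--seed S]",
    "  run      --config C.yaml", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (!length(i)) return(default)
    args[i + 1L]
  }
  cmd <- args[1]
  switch(cmd,
    simulate = {
      seed <- as.integer(opt("seed", 1)); out <- opt("out", "sim")
      n <- as.integer(opt("n", 100))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      cohort <- simulate_cohort(cohort_params(n_individuals = n, seed = seed))
      calls <- simulate_calls(cohort, seed = seed + 2L)
      utils::write.csv(cohort$trials, file.path(out, "trials_truth.csv"),
                       row.names = FALSE)
      utils::write.csv(calls$events, file.path(out, "call_events.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(seed = seed, n_individuals = n,
             params = unclass(cohort$params)),
        file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
    },
    reduce = {
      trace <- read_trace(opt("trace"))
      params <- reduction_params(
        washout_s = as.numeric(opt("washout", 60)))
      series <- reduce_trial(trace, params = params)
      out <- do.call(rbind, lapply(series, function(s) {
        data.frame(channel = attr(s, "channel"),
                   repetition = attr(s, "repetition"),
                   time_s = s$time_s, vo2_ml_h = s$vo2_ml_h,
                   flag = as.integer(s$flagged))
      }))
      utils::write.csv(out, opt("out", "vo2.csv"), row.names = FALSE)
    },
    rmr = {
      vo2 <- utils::read.csv(opt("vo2"))
      rows <- lapply(split(vo2, vo2$channel), function(ch) {
        reps <- lapply(split(ch, ch$repetition), function(r) {
          structure(data.frame(time_s = r$time_s, vo2_ml_h = r$vo2_ml_h,
                               flagged = r$flag > 0),
                    channel = r$channel[1], repetition = r$repetition[1],
                    dt_s = stats::median(diff(r$time_s)),
                    class = c("vo2_series", "data.frame"))
        })
        tr <- extract_trial_rmr(reps)
        data.frame(channel = ch$channel[1], rmr_ml_o2_h = tr$rmr_ml_o2_h,
                   repetition = tr$repetition,
                   window_start_s = tr$window[1],
                   n_reps_used = tr$n_reps_used)
      })
      utils::write.csv(do.call(rbind, rows), opt("out", "rmr.csv"),
                       row.names = FALSE)
    },
    calls = {
      events <- read_call_events(opt("events"))
      utils::write.csv(recording_features(events),
                       opt("out", "features.csv"), row.names = FALSE)
    },
    analyze = {
      trials <- utils::read.csv(opt("trials"))
      out <- opt("out", "analysis"); dir.create(out, showWarnings = FALSE)
      res <- reproduce_published(
        trials,
        calls = opt("features"),
        n_boot = as.integer(opt("nboot", 1000)),
        seed = as.integer(opt("seed", 1)))
      utils::write.csv(cbind(response = "rmr_ml_o2_h",
                             res$rmr_model$coefficients),
                       file.path(out, "table_rmr_model.csv"),
                       row.names = FALSE)
      if (!is.null(res$call_models)) {
        utils::write.csv(call_model_table(res$call_models),
                         file.path(out, "table_call_models.csv"),
                         row.names = FALSE)
      }
      rpt <- res$repeatability
      jsonlite::write_json(
        list(mean_rmr = res$mean_rmr, sd_rmr = res$sd_rmr,
             mean_rmr_mass_specific = res$mean_rmr_mass_specific,
             repeatability = list(R = rpt$R,
                                  ci = c(rpt$ci_lower, rpt$ci_upper),
                                  p = rpt$p_lrt),
             consistency_raw = unclass(res$consistency_raw)[
               c("beta", "t", "p", "n")],
             consistency_residual = unclass(res$consistency_residual)[
               c("beta", "t", "p", "n")]),
        file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
    },
    run = {
      cfg <- read_run_config(opt("config"))
      run_pipeline(cfg)
    },
    { message(usage); return(invisible(2L)) }
  )
  invisible(0L)
}
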