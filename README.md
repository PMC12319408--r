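# anuranRMR

Respirometry reduction, advertisement-call analysis and repeatability
statistics for behavioral energetics of calling frogs.

## What problem this solves

Field studies of anuran sexual signaling ask whether resting metabolic
rate (RMR) — the maintenance cost of simply being alive — constrains or
fuels an energetically expensive display. The competing *energy
management models* predict a negative (allocation), positive
(performance) or absent (independent) RMR–behavior association. Testing
them requires three measurement chains that this package implements as
one tested pipeline:

1. **Respirometry reduction.** Multiplexed push-mode flow-through traces
   (O₂, CO₂, water vapor pressure WVP, barometric pressure BP, flow rate
   FR, active-chamber marker) are reduced to oxygen consumption with lag
   alignment, baseline drift correction, the water-vapor flow correction

       FR_d = FR · (BP − WVP) / BP

   and, for excurrent air scrubbed of H₂O and CO₂ before O₂ analysis,

       V̇O₂ = 60 · FR_d · ΔO₂ / (1 − FeO₂),   FeO₂ = FiO₂ − ΔO₂

   in ml O₂ h⁻¹.
2. **RMR extraction.** Automated activity screening (MAD-based jump
   statistic), then the two-stage stable-window search: the 450-s
   interval with the lowest V̇O₂ SD, the 60-s interval inside it with the
   lowest mean, minimized across a trial's three repetitions.
3. **Call characteristics.** Call duration, pulse number, dominant
   frequency, call-by-call rate (reciprocal onset-to-onset interval) and
   call effort (duration × rate) from event tables or, optionally, raw
   16-bit WAV audio; inter-observer reliability (Pearson r + OLS slope).
4. **Statistics.** lme4-backed linear mixed models of the five call
   traits and of RMR (calendar day + mass + year, random individual
   intercept); adjusted repeatability R = V_ind/(V_ind+V_res) with a
   parametric-bootstrap CI and a boundary-corrected (½χ²₀ + ½χ²₁)
   likelihood-ratio test; and first-versus-last-trial consistency
   regressions, raw and day-residualized.
5. **Synthetic data.** A generator with known ground truth (cohort, trace
   and call levels) so every stage is testable offline.

See `vignettes/anuranRMR-methods.Rmd` for the model details, parameter
defaults and design decisions.

## Worked example

```r
library(anuranRMR)

# one simulated respirometer run: three frogs, default analyzer noise
sim <- simulate_trace(c(0.62, 0.95, 1.40),
                      trace_sim_params(burst_prob = 0), seed = 42)
sim$trace
#> respirometry_trace: 11700 samples @ 1 s, 195.0 min, channels {0,1,2,3}

series <- reduce_trial(sim$trace, params = reduction_params())
chans  <- vapply(series, attr, integer(1), "channel")
extract_trial_rmr(series[chans == 2], individual_id = "frog02")
#> trial_rmr: 0.9428 ml O2/h (rep 1, window [2284, 2344) s, 3/3 reps used)
```

The frog in chamber 2 had true V̇O₂ 0.95 ml h⁻¹; the extracted trial RMR
of 0.943 reflects the small downward bias of a minimum statistic under
analyzer noise. Cohort-level statistics on the default synthetic world:

```r
co <- simulate_cohort(cohort_params(seed = 42))
trials <- co$trials
trials$rmr_ml_o2_h <- trials$true_rmr   # or via simulate_trial_traces()

fit_rmr_model(trials, "linear")
#> lmm_result: rmr_ml_o2_h, n = 143 obs / 100 individuals
#>          term  estimate        se       t         p
#>   (Intercept)  2.006000 0.1918000  10.460 3.050e-19
#>  calendar_day -0.009818 0.0007791 -12.600 9.249e-25
#>        mass_g  0.136800 0.0246000   5.561 1.329e-07
#>      year2024 -0.199400 0.0410300  -4.859 3.139e-06
#> V_ind = 0.02232, V_res = 0.02493

repeatability(trials, "rmr_ml_o2_h", c("mass_g", "calendar_day"),
              n_boot = 1000, seed = 42)
#> repeatability: R = 0.524 (95% CI [0.293, 0.706], LRT P = 0.000163)

consistency_analysis(trials)
#> consistency (raw): N = 35, beta = 0.007245, t = 2.8, P = 0.00844
```

RMR declines over the breeding season (−0.0098 ml h⁻¹ day⁻¹ here, the
generator's −0.01 recovered within 1 s.e.), rises with mass, and is
repeatable; the positive consistency slope says same-individual RMR
measurements drift apart as the days between them grow — an effect that
vanishes in the day-residualized variant because it is carried by the
shared seasonal decline.

The full pipeline (simulate → reduce → extract → analyze, with a
checksummed manifest) runs from a config:

```r
res <- run_pipeline(run_config(seed = 1, out_dir = "demo_run"))
```

or from the shell via `inst/cli/anuranRMR run --config demo.yaml`
(subcommands: `simulate | reduce | rmr | calls | analyze | run`).

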