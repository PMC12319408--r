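Package: anuranRMR
Title: Respirometry Reduction, Call Analysis and Repeatability Statistics for
    Anuran Behavioral Energetics
Version: 0.1.0
Authors@R:
    person("Payne County", "Herpetology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for behavioral-energetics field studies of
    calling frogs. Reduces multiplexed push-mode flow-through respirometry
    traces to oxygen consumption series (lag alignment, baseline drift
    correction, water-vapor flow correction), extracts resting metabolic rate
    (RMR) by a two-stage stable-window search, computes advertisement-call
    characteristics (duration, pulse number, dominant frequency, call rate,
    call effort) from event tables or raw audio, and fits the associated
    statistical battery: linear mixed models of call traits and RMR,
    adjusted repeatability with parametric-bootstrap confidence intervals and
    a boundary-corrected likelihood-ratio test, and first-versus-last trial
    consistency regressions. A synthetic-data generator with known ground
    truth makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
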