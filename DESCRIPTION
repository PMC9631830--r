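Package: piperloop
Title: In Silico Closed-Loop Control of Continuous Piperacillin Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation platform for closed-loop intravenous delivery of the
    beta-lactam antibiotic piperacillin in virtual critically-ill patients.
    Provides a three-compartment pharmacokinetic simulator (unbound central,
    interstitial fluid and peripheral compartments) driven by piecewise-constant
    infusion schedules with sinusoidal intra-day renal-clearance variability, a
    discretized proportional-integral-derivative (PID) controller with sliding
    window anti-windup and clinical safety constraints, a one-point-calibrated
    noisy interstitial-fluid sensor model with delayed serum reference assays,
    three comparator dosing protocols (intermittent bolus, fixed continuous
    infusion, and therapeutic-drug-monitoring-titrated continuous infusion),
    and a trial engine that runs seeded virtual cohorts, computes
    time-in-therapeutic-range metrics and compares arms with paired Wilcoxon
    signed-rank tests under Holm-Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
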