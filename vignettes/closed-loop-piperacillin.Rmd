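---
title: "Closed-loop piperacillin delivery: model, controller and trial design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop piperacillin delivery: model, controller and trial design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piperloop)
```

`piperloop` simulates feedback-controlled intravenous piperacillin dosing in
virtual critically-ill patients. This vignette documents the science behind
each component, the parameters that matter, the numerical choices, and the
design decisions taken where the problem was genuinely open.

## The pharmacokinetic plant

The plant is a linear three-compartment mammillary model on drug amounts
$X_1, X_2, X_3$ (mg) — unbound central, interstitial fluid (ISF), and
peripheral:

$$
\begin{aligned}
\dot X_1 &= u(t) + K_{PC} X_3 + K_{ub} X_2 - \bigl(k_e(t) + K_{CP} + K_{isf}\bigr) X_1,\\
\dot X_2 &= K_{isf} X_1 - K_{ub} X_2,\\
\dot X_3 &= K_{CP} X_1 - K_{PC} X_3,
\end{aligned}
$$

with serum concentration $X_1/V$ and ISF concentration $X_2/V_{isf}$.
Elimination acts on the central compartment only — the standard reading of a
single elimination rate constant in a mammillary diagram — so the
steady-state serum concentration under a constant rate $R$ is $R/CL$ with
$CL = k_e V$, independent of the transfer constants. Both compartments start
at zero (treatment-naive patients). Intra-day renal-clearance variability
enters as a per-patient sinusoid,
$k_e(t) = (CL/V)\,[1 + A \sin(2\pi t/P + \varphi)]$, which has unit mean
over a period and therefore perturbs, but does not bias, total clearance.

Assumptions worth keeping in mind: kinetics are linear (no saturable
elimination), protein binding is outside the model (all concentrations are
unbound), and tazobactam is not modelled.

### Numerical integration

Infusion schedules are piecewise-constant; a bolus is a finite-rate segment
(4,000 mg over 20 min = 12,000 mg/h for 1/3 h), never an impulse.
Integration uses the adaptive Dormand–Prince RK45 method (`deSolve`, with a
compiled right-hand side), absolute and relative tolerances $10^{-6}$, and a
hard restart at every schedule breakpoint: discontinuous forcing invalidates
embedded error estimates if stepped across, so each constant-rate segment is
integrated as its own initial-value problem. Amounts are clipped to zero on
output; an excursion below $-10^{-6}$ mg raises an error instead of being
silently clipped, to separate numerical noise from genuine bugs. The test
suite cross-checks the integrator against an independently coded fixed-step
explicit-Euler oracle at $10^{-4}$ h, against the analytic steady state, and
against mass conservation with elimination switched off.

## The virtual population

Cohorts are sampled independently per parameter from **moment-matched
lognormal** distributions. The published population moments for septic
critically-ill patients are used as defaults: $V$ 17.0 (SD 8.0) L, $CL$
14.0 (SD 8.4) L/h, $V_{isf}$ 12.4 (SD 12.8) L. With coefficients of
variation up to ~103%, a normal distribution would produce negative volumes,
hence the lognormal default (a rejection-sampled truncated normal is
available as `family = "truncnorm"`). $k_e$ is derived per patient as
$CL/V$.

Choices that could not be taken from published values:

* **Transfer constants.** No population moments are published for
  $K_{CP}, K_{PC}, K_{isf}, K_{ub}$. The defaults (means 2.0, 1.5, 1.0,
  1.5 h⁻¹, CVs 50%) are placeholders calibrated so that ISF concentration
  traces lag and under-shoot serum, as observed clinically with
  microdialysis; they are configuration knobs, never constants in the model
  core.
* **Intra-day sinusoid.** Amplitude $A \sim U(0, 0.3)$ (circadian-scale
  clearance swings up to ±30% are physiologically plausible in critical
  illness), period fixed at 24 h, phase uniform. All three are configurable.
* **Independence.** Parameters are sampled without covariance (none is
  published). This understates the correlation between clearance and volume
  seen in real patients and is a documented limitation.
* **Creatinine clearance** (mean 98.4, SD 50.2 ml/min) is recorded as
  per-patient metadata but does not drive elimination — no covariate model
  is fitted.

What the generator emulates: wide inter-individual PK variability,
circadian clearance swings, sensor and assay noise. What it does not:
parameter correlations, non-stationary physiology (shock, renal replacement
therapy), sensor drift/fouling, pump artefacts. Passing trials here
therefore demonstrate controller robustness to the modelled variability
only, not clinical performance.

## Sensor, assay and one-point calibration

The ISF sensor reads every 0.5 h with multiplicative Gaussian noise floored
at zero. Its error magnitude is not yet established for minimally invasive
beta-lactam sensors; the default CV is 10% and configurable. The serum
reference assay has a 5% CV (an acceptable chromatographic assay by
regulatory criteria), a 1-h laboratory turnaround, and a 1 mg/L lower limit
of quantification.

Because ISF and serum concentrations differ systematically, the controller
operates on a serum-scale estimate obtained by one-point calibration: at
calibration instant $i$, the factor $m_i = M_{serum}(i-t)/M_{isf}(i-t)$
pairs the serum sample with the ISF reading *from the same (delayed)
instant*, and thereafter $C_V(k) = m_i M_{isf}(k)$. Calibration never uses
information newer than $i - t$. Recalibration occurs every 6 h from
controller start — a TDM-like cadence; the interval is a knob. If the ISF
reading sits at or below the quantification floor the calibration is
skipped and the previous factor retained.

The rule that the PID integral resets "when sensor error exceeds 30%" needs
an observable surrogate: the controller cannot measure its own error against
truth. We operationalize it as the relative jump of the calibration factor,
$|m_{new} - m_{old}|/m_{old} > 0.30$ — i.e. the calibrated ISF estimate
disagreed with the fresh serum reference by more than 30%. This is an
interpretation, and is flagged as such.

## The PID controller

Discretized at $\Delta t = 0.5$ h:

$$
u_k = B_k \pm \Bigl[ K_p e_k + K_i \sum_{j=k-w/\Delta t}^{k} e_j\,\Delta t
      + K_d \frac{e_k - e_{k-1}}{\Delta t} \Bigr],
\qquad e_k = C_V(k) - SP,
$$

with rectangle-rule integral over a 6-h sliding window (anti-windup),
backward-difference derivative, basal profile $B$ fixed at the 300 mg/h
initial rate, set point $SP = 60$ mg/L (midpoint of the 20–100 mg/L control
range), and gains $K_p = 5$, $T_d = 1$ h, $T_i = 0.5$ h under the
convention $K_d = K_p/T_d$, $K_i = K_p T_i$ (a `textbook_gains` switch
provides the reciprocal arrangement).

**The sign of the correction is the one genuinely open design point.** With
$e = C_V - SP$ and positive gains entering with a plus sign, a
concentration above target *raises* the infusion rate — positive feedback.
On a one-compartment toy plant ($k_e = 0.5$ h⁻¹, $V = 15$ L) that form
drives the loop onto its constraints instead of to the set point, while the
subtractive form settles within ±10% of the set point and stays there. The
default is therefore `error_sign = "negative_feedback"` (corrective terms
subtracted, equivalent to $e = SP - C_V$); the additive form remains
available as `error_sign = "as_printed"` and its arithmetic is unit-tested.

Safety constraints, in order of application: (1) delivery halts ($u = 0$)
whenever $C_V$ exceeds the 100 mg/L upper control bound — highest
precedence, not latched, re-evaluated each sample; (2) cap at 5× basal;
(3) floor at 50% of the previous commanded rate, where "previous" is the
last *nonzero* commanded rate so that a halt does not drag the floor to
zero; (4) non-negativity. At the first controlled sample the derivative is
zeroed ($e_{k-1} := e_k$) to avoid a spurious kick, and the floor references
the open-loop basal. A no-op `adapt_tuning()` hook marks where on-line
re-tuning would attach; with the wide control range used here it is never
required.

Note the finite integral window implies a nonzero steady-state offset: the
loop equilibrates where $CL \cdot C = B + (K_p + K_i w)(SP - C)$, i.e.
below the set point for high-clearance patients — by design a conservative
bias away from toxicity.

## Dosing protocols and the trial

* **Protocol 1 (bolus):** 4,000 mg over 20 min at 0, 6, 12, 18, 24 h
  (a 30-h dose would deliver outside the window); 20,000 mg total.
* **Protocol 2 (rate):** 4,000 mg loading over 20 min, then 666.7 mg/h from
  the end of the loading infusion to 30 h (the 2.5-h start gap applies only
  to the closed-loop arm).
* **Protocol 3 (rate-titrate):** protocol 2 plus ±500 mg/6 h adjustments at
  6, 12, 18, 24 h, decided by a serum measurement drawn 1 h earlier (same
  5% assay), compared against the 60 mg/L midpoint; an exactly-at-target
  measurement leaves the rate unchanged; the rate is floored at 0.
* **Closed:** loading dose, open-loop 300 mg/h basal until 2.5 h, then the
  PID loop at 0.5-h samples.

Metrics are computed on the **serum** trace over the full 0–30 h window
(no lead-in exclusion): evaluation targets are serum ranges even though
control acts on calibrated ISF. Time fractions are exact for the
piecewise-linear interpolant — crossings between grid points are counted at
interpolated times — and MEAN is the trapezoidal time average. DOSE is
total delivered mass divided by the horizon (`dose_metric = "mean_rate"`);
a median-of-hourly-bins alternative is provided because the dose-accounting
convention behind published per-hour figures is not stated and no obvious
convention reproduces them exactly (e.g. 20,000 mg/30 h = 666.7, not
671.1).

Arms are compared with two-sided paired Wilcoxon signed-rank tests (exact
when the sample permits; zero differences dropped, ties mid-ranked — the
conventions matter at $n = 20$) and Holm's step-down adjustment within each
metric's family of six pairwise comparisons ($\alpha = 0.05$); a `global`
family option widens the family to all metrics. All-zero difference vectors
report $p = 1$. Population summaries use linear-interpolation quantiles
(R type 7; other environments' default quantile conventions differ
slightly).

## Problem sizes, determinism and runtime

The trial engine runs 20-patient cohorts over 30 h with a 0.1-h metric
grid; the acceptance script averages cohort medians over ten consecutive
cohort seeds, reflecting that a single 20-patient cohort median of a
skewed metric is itself highly variable (the fixed-rate arm's
time-in-range median spans tens of percentage points across cohorts, in
line with the wide interquartile ranges typical of critically-ill PK
data). Every random draw — population sampling, sinusoid realization,
sensor and assay noise — descends from the single user seed; patients carry
private sub-seeds so that arms and patients are independently reproducible,
and results are bitwise identical across runs.

## Known limitations

* The transfer constants and the ISF sensor error are placeholders; absolute
  ISF dynamics (and anything downstream of them, such as calibration
  quality) should not be over-interpreted.
* Parameters are sampled independently; real PK parameters correlate.
* Under the lognormal population defaults, many sampled patients already sit
  in the upper half of the 32–64 mg/L evaluation range at the fixed
  continuous rate; midpoint-seeking titration then steps some of them across
  the 64 mg/L bound, so the titrated arm's time-in-range relative to the
  other arms is sensitive to the cohort's clearance distribution — a real
  20-patient cohort with differently spread clearances can rank it higher.
* Microdialysis relative recovery, sensor drift and pump artefacts are not
  modelled; the adaptive-tuning mechanism is a stub.
* In-silico trials inform design; they are not a substitute for clinical
  evaluation.
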