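---
title: "The EASI cascade: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The EASI cascade: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(easi)
```

## The model

COPD natural history is represented as a strictly feed-forward cascade of
four stages, each summarized by one dynamic variable:

* **Exposure** E(t), packs/day. A closed-form product of two logistics of
  age: a rising one for smoking initiation and, for quitters, a mirrored
  falling one for cessation. Each logistic is parameterized by the span of
  its 5%–95% transition, equal to the printed "time to maximal exposure" /
  "time to complete quitting", centred mid-window. Never-smokers have E ≡ 0.
* **Activity** A(t) ∈ [0, 1], the inflammatory response. Its steady-state
  target is a *gated* logistic of exposure — exactly zero at or below the
  activity trigger, so individuals who never exceed the trigger mount no
  response at all — floored, once any activity has been mounted, at
  `persistence_after_quitting` × the running peak of A. The floor is the
  hysteresis that lets inflammation outlive smoking cessation.
* **Severity**: FEV1 F(t), liters. Past the plateau age,
  dF/dt = −(r(A)/F₂₀)·F, with
  r(A) = normal + (max − normal)·σ(slope·(A − trigger)) for A above the
  severity trigger and r(A) = normal below it. The ml/yr rates of the
  parameter tables are therefore *initial-slope* rates at F = F₂₀; the
  trajectory itself is exponential, which keeps FEV1 positive over a 90-year
  life even at the maximal 100 ml/yr rate.
* **Impact** I(t) ∈ [0, 1], perceived dyspnea. Steady-state target
  σ(slope·(trigger − F/F_ref(age))), a decreasing logistic of lung function
  on the fractional %-of-reference scale.

A(t) and I(t) relax towards their targets through first-order linear ODEs
with time constants `tau_activity` and `tau_impact`:
dA/dt = (A_target − A)/τ. Downstream stages never influence upstream ones;
this isolation is asserted bit-exactly in the tests.

"% ref" always means percent of the *age-matched* internal reference
trajectory: F_ref is 4.0 L up to the plateau age and then declines under the
same first-order law with zero activity (30 ml/yr initial slope,
`reference_fev1()`). This reading — rather than percent of the individual's
own age-20 value — is what makes a never-smoker sit at 100% at every age and
keeps the continuous smoker's ~45%-at-80 endpoint consistent with a ~50
ml/yr mean cohort decline.

## Parameters that matter

Per individual (see `?easi_params`): onset age, maximal dose (packs/day),
time to maximal dose, quit age and quitting duration; activity trigger
(packs/day), slope, and persistence fraction; normal and maximal decline
(ml/yr), severity trigger (activity fraction) and slope; FEV1 at 20 (L);
impact trigger (fraction of reference FEV1; values above 1 describe
individuals who perceive symptoms within the normal range) and slope.
Percent-printed quantities are stored as fractions.

Shared constants (`?easi_constants`): Euler step `dt = 0.2` yr; reference
anchor 4.0 L at 20; plateau end 25 yr (the Fletcher–Peto convention that
adult decline begins in the mid-twenties; the simulation holds FEV1 at its
age-20 value throughout 10–25, so impaired lung development enters as the
age-20 initial condition); window 10–90 yr; relaxation times
`tau_activity = tau_impact = 1` yr, chosen small so activity tracks exposure
"rapidly" on the life-course time scale. All are configurable.

## Numerical scheme

Explicit Euler, strictly left-endpoint: all stage targets are evaluated at
the current state, then every variable is advanced at once. Pack-years
accumulate by the left-endpoint sum (1 pack/day for 1 year ≡ 1 pack-year).
A and I are clamped to [0, 1] after every step — they are fractions of a
maximal response by construction. FEV1 reaching zero or below raises an
error (the model has left its validity domain) rather than continuing
silently. Halving `dt` from 0.2 to 0.1 moves FEV1 at age 80 by under 2 ml in
all six built-in scenarios (the tests require ≤ 10 ml), so the default step
is comfortably inside the convergence regime. Decade summaries are *point
samples* at the decade ages (which lie exactly on the 0.2-yr grid), not
decade means, so tabulated anchors can be read off directly.

## Design choices that were genuinely open

* **Gated vs plain activation.** Activity uses the gated form
  g(d) = tanh(slope·d) for d > 0 (the logistic rescaled from its upper
  half-range onto [0, 1]); Impact uses the plain logistic. The asymmetry is
  deliberate: gating Activity makes "never exceeded the trigger" mean
  literally zero inflammation, while the shallow ungated Impact logistic is
  what places the continuous smoker near two-thirds of maximal impact at 80.
  A side effect worth knowing: a perfectly healthy individual has a nonzero
  impact steady state (σ(2·(0.8 − 1)) ≈ 0.40), i.e. the scale should be read
  as relative position between floor and ceiling of the perception range,
  not as absolute symptom burden.
* **Threshold severity law.** r(A) jumps onto the logistic branch only above
  the severity trigger and is exactly `normal_decline` below it. The hard
  threshold (rather than a rescaled-to-zero logistic) keeps subclinical
  activity from causing excess decline — never-smokers then coincide with
  the reference trajectory — while preserving the logistic dose–response
  that yields the canonical smoker endpoint. The jump at the trigger is a
  discontinuity in r, but trajectories cross it in a single step in
  practice.
* **Severity normalization.** r(A) is normalized by the *individual's*
  F₂₀, so the printed rates are initial-slope rates for that individual;
  using the 4.0 L population anchor instead would only matter for the
  low-F₂₀ profiles.
* **Initial impact.** I starts at 0 at age 10 and relaxes to its healthy
  steady state within a few years; by mid-life the initialization is
  forgotten.

## The population layer

`population_spec()` draws individuals from independent truncated normals
centered on the susceptible-continuous-smoker values with a common CV of
0.15, truncated to the parameter invariants (`max_decline` is additionally
truncated below at the draw's `normal_decline`). Quitting-stage parameters
are not dispersed (the center profile is a non-quitter); non-smoking
populations zero the exposure stage. Each draw is a deterministic function
of `(seed, draw_index)` via inverse-CDF sampling on a derived substream, so
ensembles are bitwise reproducible and a single draw can be reproduced
without regenerating the cohort. The lower limit of normality is a
configurable fraction (default 0.80) of the internal reference trajectory —
a synthetic stand-in for published reference-equation LLNs, adequate for
relative comparisons only.

`calibrate_population()` is a seeded, derivative-free random search over the
common CV (optionally selected parameter centers), minimizing the relative
squared error of the ensemble mean/SD FEV1 curves against user-supplied
targets plus an optional mean-decline target. Candidate ensembles reuse the
spec's seed (common random numbers), making the loss surface deterministic;
at the generating specification the loss is exactly zero, which is the
parameter-recovery oracle the tests use. If no candidate improves on the
starting point the input specification is returned with a diagnostic.

## What the generator does and does not emulate

The synthetic cohorts reproduce the qualitative structure of population
spirometry — a plateau, roughly exponential adult decline, dispersion
growing with age, smokers shifted below non-smokers — and a mean adult
decline near 50 ml/yr in persistent smokers under the default calibration.
They do not model birth cohorts, measurement error, mortality selection
(fast decliners remain in the cohort to 90), exacerbations, treatment, or
correlated parameters; passing tests therefore demonstrate internal
consistency of the simulator, not fidelity to any real cohort.

## Problem sizes

The test suite runs single trajectories (401 steps at dt = 0.2), ensembles
of 1–1,000 models, and calibration searches of 5–30 evaluations on 30–80
model ensembles; the acceptance script uses the full 1,000-model ensemble.
These sizes keep the whole suite in the tens of seconds while leaving the
Monte Carlo error of the ensemble mean decline near 0.2 ml/yr (SD ≈ 6 ml/yr
across models).

## Known limitations

Deterministic within an individual (all stochasticity lives in the
parameter draws); no feedback or adaptation (symptom-driven behaviour
change, rehabilitation); severity is FEV1-only; the activation forms above
the trigger are smooth but the severity rate has a step at its trigger; the
reference trajectory and LLN are internal constructs, not published
reference equations — comparisons against real spirometry need the user's
own targets via `calibrate_population()`.
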