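---
title: "Cause-specific versus subdistribution safety analysis: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cause-specific versus subdistribution safety analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crsafety)
```

## The question the package answers

In a two-arm trial where death competes with the adverse event (AE) of
interest, the measured "safety effect" depends on which hazard is modelled.
The **cause-specific** hazard is the instantaneous AE rate among patients
who are still alive and event-free; Cox regression estimates it by censoring
patients at death. The **subdistribution** hazard keeps patients who died in
the risk set; Fine–Gray regression estimates it, and its coefficient is the
one that moves the cumulative incidence function (CIF). A treatment that
extends survival mechanically inflates its arm's AE incidence, so the two
settings can disagree about the *conclusion* of a safety comparison, not
just its magnitude. `crsafety` simulates trials across a grid of effect
sizes, fits both models to every replicate, pools, classifies and
cross-tabulates the disagreements.

## The trial simulator

Each simulated trial has `2 * n_per_arm` patients (default 600, 1:1). Every
patient carries two independent latent exponential times — AE and death —
with arm- and cause-specific constant hazards set from target medians via
`h = log(2) / median` (months). The observed record is the earliest of the
two latent times and the administrative censoring horizon (default 30
months); the event code identifies the winner (0 censored, 1 AE, 2 death).

Fixed design parameters and why:

| parameter | default | meaning |
|---|---|---|
| `n_per_arm` | 300 | 600-patient trial, a typical phase-III size |
| `median_death_verum` | 20 months | death HR verum/control = 0.5 — |
| `median_death_control` | 10 months | the survival advantage that drives switching |
| `censor_time` | 30 months | common administrative end of follow-up |
| grid | 1–20 months × 1–20 months | AE medians per arm; 400 conditions |
| `reps` | 1000 | replications pooled per condition |
| `alpha` | 0.05 | two-sided significance boundary (p = 0.05 counts) |

For exponential marginals, drawing independent latent times is equivalent to
any mechanism with the same constant cause-specific hazards, so nothing
observable depends on the latent-failure-time interpretation; a
generalisation to non-exponential families would have to commit to one.
Degenerate rates are allowed (`median = Inf` gives a cause that never
fires), which is how the tests construct competing-risk-free data. A latent
time exactly equal to the censoring time — possible only through floating
point — is treated as censored.

What the generator does *not* emulate: non-constant hazards (AEs that
cluster early under treatment, frail patients dying early), informative or
staggered censoring, covariates beyond the treatment arm, and recurrent or
multiple AE types. Conclusions drawn from the grid are statements about this
idealised design; the pipeline's agreement with its analytic truths shows
the estimators and bookkeeping are right, not that real trials behave
exponentially.

## Estimation

Both settings are fitted by one Newton–Raphson engine maximising the partial
likelihood for a single binary covariate, so they share every numerical
convention and differ only in the risk set:

- **Cause-specific**: competing events are recoded as right-censored at
  their time; the ordinary Cox risk set applies.
- **Subdistribution**: a patient dying at `s` remains at risk for every AE
  time in `[s, censor_time]`. Because the design censors everyone
  administratively at one known time, this is the *censoring-complete* form
  of the Fine–Gray estimating equation — every potential censoring time is
  known, and no inverse-probability-of-censoring weights are needed; the fit
  is exactly a Cox fit on data in which deaths are moved to
  (`censor_time`, censored). Data with earlier censoring are rejected with
  an explicit error rather than silently mis-weighted; the IPCW extension
  for random censoring is out of scope.

Numerical conventions, applied identically in both settings:

- **Ties**: Efron's correction. The continuous generator produces ties with
  probability zero, but user-supplied or rounded data may not.
- **Convergence**: stop when |score| < 1e-9 or the step falls below 1e-10,
  maximum 50 iterations, with step-halving as a guard (the objective is
  concave; halving essentially never triggers).
- **Monotone likelihood**: when all events of interest fall in one arm the
  MLE is infinite. The estimate is capped at |log HR| = 15, flagged
  non-converged, and excluded from pooling with a logged count. At 600
  patients per trial such replicates are rare to absent; the cap prevents a
  single divergent replicate from dominating a pooled variance.
- **Inference**: Wald on the log-HR scale, model-based (inverse-information)
  standard errors in both settings, keeping the two fits maximally
  comparable. `cmprsk::crr` reports a sandwich variance for the Fine–Gray
  model instead; at this design's size the two differ by well under a
  percent, which the test suite checks.
- **Baseline**: a Breslow-type cumulative (sub)hazard on the extended risk
  set backs `predict_cif()`, `F(t|x) = 1 − exp(−Λ0(t) e^{γx})`.

The fitters are audited two independent ways: brute-force grid maximisation
of explicitly-enumerated partial likelihoods on small fixtures, and
`survival::coxph` / `cmprsk::crr` on simulated data.

One modelling fact worth stating plainly: under this design the
subdistribution hazards are *not* proportional between arms (the death-rate
difference makes the true subdistribution hazard ratio time-varying), so the
Fine–Gray coefficient is a working-model summary and its predicted CIF
carries a small asymptotic bias at such conditions. The package tests CIF
prediction for consistency where the model is correctly specified (identical
arms) and documents — rather than hides — the misspecification elsewhere,
since that misspecification is precisely the phenomenon the grid experiment
quantifies.

## Non-parametric estimators

`kaplan_meier()` (with Greenwood variance), `nelson_aalen()` (Poisson-type
variance) and `aalen_johansen_cif()` support the naive-versus-competing
incidence comparison: 1 − KM treats death as censoring and estimates the AE
risk "as if nothing else could happen", while the Aalen–Johansen CIF
estimates the fraction of patients who actually experience the AE first.
The suite asserts the exact identities: AJ reduces to 1 − KM with no
competing events, the cause-specific CIFs and all-cause survival sum to one
at every event time (to 1e-12), 1 − KM dominates the AJ CIF whenever deaths
are present, and `exp(−NA) ≥ KM` pointwise. Ties between deaths and AEs at
one time are processed in the same increment; censoring at an event time is
ordered after the events. A pointwise variance for the AJ curve is not
provided; no pipeline decision uses curve variances.

## Pooling and classification

Replicate log-HRs are pooled by Rubin's rules (mean `Q̄`, within-variance
`W` = mean squared SE, between-variance `B`, total `T = W + (1+1/m)B`), with
the classical degrees of freedom `ν = (m−1)(1 + W/((1+1/m)B))²` and a
Student-t reference; `B = 0` falls back to the normal. The Barnard–Rubin
small-sample correction is deliberately not used — at `m ≥ 100` it is
indistinguishable. Note what pooling over *independent* replicates implies:
`B` estimates the full between-trial sampling variance, so `T ≈ W + B` does
not shrink as `m` grows. The pooled test behaves like a single trial's test
with a slightly inflated variance, which is why condition classifications
are stable between 100 and 1 000 replications and why the package's
reduced-replication default for testing (`reps = 100`) reproduces the
full-scale classification map; the experiment driver and the tests use
400 conditions × 100 replications as their standard problem size.

Each pooled condition is classified **superiority** (HR < 1, p ≤ 0.05),
**inferiority** (HR > 1, p ≤ 0.05) or **equivalence** (p > 0.05, an absence
of evidence, not a TOST equivalence claim), per setting; the pair maps to
the switching category 1–9 (rows: cause-specific outcome, columns:
subdistribution outcome, row-major). Boundary conventions: p exactly 0.05
is significant; HR exactly 1 with p ≤ 0.05 is unreachable under Wald
inference, so no tie-break is needed.

On "pessimism": switching is one-directional — no condition moves toward a
more favourable category under the subdistribution reading (categories 3,
4, 7 and 8 stay empty), and wherever verum is truly safer or equal the
pooled HR_sd is at least the pooled HR_cs. On the truly *inferior* half of
the grid both estimates exceed 1 and the subdistribution estimate is the
one attenuated toward 1 — the extended risk set dilutes extreme hazard
ratios on both sides of the null — so a blanket inequality
HR_sd ≥ HR_cs across the whole grid does not hold and is not asserted.

## Reproducibility

One master seed drives everything: `replicate_seeds()` expands it into a
per-(condition, replicate) seed table, so any single replicate can be
reconstructed in isolation, and `run_experiment()` writes a manifest from
which a rerun is byte-identical. The command-line wrapper
(`inst/scripts/run-grid.R`) and the acceptance script
(`scripts/acceptance.R`) are thin shells over the same functions.

## Known limitations

- Exponential event times only; the constant-hazard assumption is the
  design's simplification, not a recommendation.
- One binary covariate; no stratification, no covariate adjustment.
- Fine–Gray fitting requires common administrative censoring
  (censoring-complete); random censoring is rejected, not approximated.
- "Equivalence" is non-significance at `alpha`, with the usual caveats.
- Death parameters are fixed across the grid; sample size is fixed per
  trial. Varying either is a one-line config change but is outside the
  shipped design.
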