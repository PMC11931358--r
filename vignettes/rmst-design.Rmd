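---
title: "Power, sample size and blinded re-estimation for RMST-based tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power, sample size and blinded re-estimation for RMST-based tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmstaug)
```

## The estimand and the two tests

We observe n i.i.d. copies of (X, Δ, Z, V): follow-up time X = min(T, C),
event indicator Δ = I(T ≤ C), randomized arm Z ∈ {0, 1} with
P(Z = 1) = π, and baseline covariates V. Randomization makes V ⊥ Z, and the
usual survival assumption C ⊥ T | Z is maintained; the power machinery
additionally assumes a common censoring distribution C ⊥ Z, the same
assumption the event-driven logrank design makes.

The treatment contrast is the RMST difference
θ = ∫₀^τ S₁(t)dt − ∫₀^τ S₀(t)dt with a truncation time τ that is fixed in
the protocol, in the time units of the data. θ̂ plugs in the arm-wise
Kaplan–Meier curves; all integrals of step curves are exact segment sums,
never quadrature on a grid.

Two consistent estimators of Var{√n(θ̂ − θ)} are provided:

* **plug-in** (`var_plugin`): Σ_z ∫₀^τ {∫ₜ^τ Ŝ_z}²/Ȳ_z(t) dΛ̂_z(t), a sum
  over the arm's event times, with the Nelson–Aalen increments and the
  at-risk fraction Ȳ_z(t) normalized by the *total* n (so the arm's
  allocation share is inside Ȳ_z, not a separate factor);
* **score** (`var_score`): n⁻¹ Σ Ĥ_i², where Ĥ_i is the per-subject
  martingale-residual integral
  Ĥ_i = −Z_i ∫₀^τ w₁(t) dM̂_{1,i}(t) + (1 − Z_i) ∫₀^τ w₀(t) dM̂_{0,i}(t),
  w_z(t) = ∫ₜ^τ Ŝ_z du / Ȳ_z(t).

`rmst_test()` uses the score form by default. The two estimators agree
asymptotically (the suite checks 5% relative agreement at n = 10⁴), but the
score form is the coherent default because the augmented test is built from
the same scores: the augmented estimator
θ̂_aug = θ̂ − n⁻¹ Σ (Z_i − π) ĉᵀV_i uses the projection coefficient
ĉ = {π(1−π) Σ V_iV_iᵀ}⁻¹ Σ (Z_i − π)V_i Ĥ_i and the variance
n⁻¹ Σ {Ĥ_i − (Z_i − π)ĉᵀV_i}². With equal allocation (Z − π)² ≡ 1/4, so ĉ
is the exact least-squares minimizer and σ̂²_aug ≤ σ̂₂² holds for every
dataset, not just in expectation — the suite asserts it as an exact
property. Standard and augmented tests therefore differ only by the
augmentation term.

Covariates enter raw (not centered or rescaled). The estimate is invariant
under any invertible linear reparameterization of V, so the optional
`standardize` flag (scaling columns by their standard deviations, for
conditioning only) cannot change the answer. Collinear covariates are a
hard error by default — silently pseudo-inverting hides a specification
problem; `allow_singular = TRUE` opts in explicitly.

## Local power and what it needs

Under a local (1/√n) alternative with RMST difference θ_alt, both test
statistics are asymptotically normal and the two-sided power at level α is

Φ(z_{α/2} − θ_alt/v) + 1 − Φ(z_{1−α/2} − θ_alt/v),

with v² = σ̃₁²/n for the standard test, where

σ̃₁² = {π(1−π)}⁻¹ ∫₀^τ {∫ₜ^τ S₀ du}² / {S₀(t) G(t)} dΛ₀(t),

and v²_aug = {σ̃₁² − π(1−π)e²}/n for the augmented test. Two features make
this usable at the design stage: σ̃₁² involves only the *control* survival
law and the censoring law (no treatment-arm curve needs to be guessed), and
e² — the variance explained by the covariates, a quadratic form between the
null martingale-residual integrals and V — involves no treatment
assignment either. z_{α/2} denotes the lower-tail quantile (a negative
number), so θ_alt = 0 gives power exactly α; the suite asserts this to
1e-12. The augmented power formula is derived for equal allocation, and
`predicted_power()` refuses e² > 0 with π ≠ 1/2 rather than extrapolating;
the estimator itself accepts general π.

### Estimating the inputs from data

`design_power()` (control-only reference data) and `blinded_inputs()`
(pooled mid-trial data) estimate both quantities from a single-group
dataset: S₀ by Kaplan–Meier, G by reverse Kaplan–Meier (censorings as
events; at ties events leave the risk set first), and the per-subject
scores g_i with weight ∫ₜ^τ Ŝ₀du / Ȳ(t). Under the events-first tie
convention Ŝ(t−)Ĝ(t−) equals the at-risk fraction Ȳ(t) *exactly*, so this
weight is precisely the plug-in of ∫ₜ^τ S₀/{S₀(t)G(t)}.

Two consistent plug-ins of σ̃₁² then exist: the step-sum integral of the
display above, and the score form {π(1−π)}⁻¹ · mean(g_i²). We use the
**score form** for all dataset-driven design quantities. It is the exact
single-group analogue of the score variance that the tests themselves use,
so the design stage, the blinded review and the final analysis all rest on
one variance construction; empirically the two plug-ins differ by about 1%
at reference sizes of a few hundred. The integral form remains the
definition for curve or parametric specs via `sigma_tilde_sq()` — including
when a known censoring law (e.g. administrative uniform censoring) is
supplied instead of the reverse-KM estimate — and parametric specs are
integrated by adaptive quadrature at relative tolerance 1e-8.

e² is estimated as {π(1−π)}⁻² (1/n⁺) aᵀB⁻¹a with a = Σ g_iV_i and
B = Σ V_iV_iᵀ. The {π(1−π)}⁻² factor puts ê² on the scale on which the
augmented variance reduction is π(1−π)ê²; the package validates this scale
through the internal consistency of its own results (the design-stage
predicted power of the augmented test tracks the empirical power of the
augmented test in the replication suite). ê² ≥ 0 always, it is exactly 0
for a constant covariate (martingale residuals sum to zero at every event
time), and it can only grow when covariates are added — which is why
`stepwise_covariates()` returns the whole forward path with per-stage
predicted power and leaves the saturation cut to the user rather than
applying an arbitrary stopping rule.

## Blinded re-estimation

`reestimate_n()` takes a pooled snapshot of n_mid subjects followed to τ,
re-estimates σ̃₁² and ê² from it, scans n = n_mid, n_mid + step, … and
returns the first n whose predicted power reaches the target. Defaults:
target 0.8, step 10 (sizes are reported to the nearest ten, as trial
protocols do). The snapshot must not contain an arm column — blindness is
enforced by the schema, with an explicit `strip_arm = TRUE` override — and
the final size never drops below the n_mid subjects already observed.
"Followed to τ" is taken as administratively complete follow-up of the
snapshot subjects; partial-follow-up snapshots are out of scope.

## The synthetic-data generator

`sim_trial()` implements six scenarios on a fixed design: control-arm
exponential with rate λ₀ = −log(0.2)/5 (five-"year" survival 0.2), τ = 5,
independent Uniform(0, 8) administrative censoring, equal allocation.
Scenarios 1a/1b are null; 2a/2b apply a hazard ratio of 0.7 (true RMST
difference 0.5142); 3a/3b make the treatment hazard λ₀ before t = 1 and a
solved λ₂ ≈ 0.159 after, calibrated by `solve_lambda2()` (bisection on the
closed-form piecewise-exponential RMST, plug-back residual below 1e-10) so
the true difference matches scenario 2. Covariates are V_j = b_j + ε_j
(marginally N(0, 2)); under setting "a" the failure time is linked to them
through the Gaussian copula U = Φ₃(b₁ + b₂ + ε), under "b" U = Φ₁(ε) is
independent of them. The failure time is the inverse CDF of the arm's
marginal law applied through −log(U), so the stated marginal laws hold
exactly in both settings. Reference sets draw from the control law only;
the "mis-matched" variant keeps only subjects with V₁ < 1 and V₂ < 1, a
deliberately biased sample that degrades the design-stage prediction.

One master seed drives everything; study functions derive per-replicate
seeds by a counter scheme so replicates are order-independent.

What the generator does *not* emulate: staggered accrual (censoring is a
calendar-free uniform draw), covariate-dependent censoring, categorical or
skewed covariates, and any miscoding or missingness. Passing tests
therefore demonstrate correctness of the estimators and calibration under
clean proportional- and non-proportional-hazards laws, not robustness to
real-data pathologies.

## Numerical conventions and degenerate inputs

* Ties: events at a time are counted against the at-risk set that still
  includes same-time censorings; the reverse-KM risk set removes same-time
  events first. This fixes every estimate bit-for-bit.
* Follow-up shorter than τ: curves are extended flat with a warning
  (`extend = "flat"`); `extend = "error"` is the strict mode. The built-in
  designs (censoring support 8 > τ = 5) essentially never trigger it.
* No events in [0, τ]: variances are zero and the tests refuse to run
  ("no events within truncation window"); σ̃₁² returns 0 with a warning.
* Grid search: `required_n()` scans an arithmetic grid and reports the
  power at the failure point when the target is unreachable, rather than
  extrapolating.
* All probability integrals on parametric specs use `stats::integrate`
  (rel. tol 1e-8); uniform censoring with support not covering τ is
  rejected because the integrand diverges.

## Problem sizes in the suite

The replication harness runs the full study at 10,000 replicates in the
acceptance script (about 45 s on one CPU thanks to the vectorized
counting-process path), while the test suite uses 2,000 replicates for
size/power, 1,000 reference sets for the design-stage average and 1,000
replicates of the re-estimation loop, with tolerances widened to the
corresponding binomial and Monte-Carlo standard errors.

## Limitations

Left truncation, interval censoring, competing risks and stratified tests
are out of scope, as are group-sequential or unblinded interim analyses,
unequal-allocation augmented power, accrual modeling beyond what the user
encodes in G, and data-dependent choice of τ. The local power formula is an
approximation that degrades for very large effects — where the required n
is small and a blinded review is of limited value anyway.
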