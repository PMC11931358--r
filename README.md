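# rmstaug

Design and analysis of randomized clinical trials that compare two arms by
the **difference in restricted mean survival time (RMST)** — the area
between the survival curves up to a prespecified truncation time τ — with a
focus on the questions a trial statistician faces *before* the data exist:

* How much power does the RMST-difference test have, and how many subjects
  does it need, when only the control-arm survival curve and the censoring
  distribution can be guessed?
* How much can baseline covariates buy? The **augmented** RMST test
  subtracts a mean-zero projection of the influence scores onto the
  treatment-centered covariates, shrinking the variance without touching
  the estimand.
* What if the design-stage guesses were wrong? A **blinded mid-trial
  sample-size re-estimation** recomputes the required n from pooled data
  without ever looking at the treatment assignments.

## The statistics in brief

For arm z with survival function S_z, the RMST is θ_z = ∫₀^τ S_z(t)dt,
estimated by the area under the Kaplan–Meier curve, and the contrast is
θ = θ₁ − θ₀. The variance of √n(θ̂ − θ) is estimated either by the plug-in
form

σ̂₁² = Σ_z ∫₀^τ {∫ₜ^τ Ŝ_z du}² / Ȳ_z(t) dΛ̂_z(t)

or by the score form σ̂₂² = n⁻¹ Σ Ĥ_i², where Ĥ_i are per-subject
martingale-residual integrals and Ȳ_z is the at-risk fraction (normalized
by the total n). The augmented estimator is θ̂_aug = θ̂ − n⁻¹Σ(Z_i − π)ĉᵀV_i
with ĉ the least-squares projection of Ĥ on (Z − π)V; its variance is
n⁻¹Σ{Ĥ_i − (Z_i − π)ĉᵀV_i}².

Under a local alternative the power of a two-sided α-level test is

Φ(z_{α/2} − θ_alt/v) + 1 − Φ(z_{1−α/2} − θ_alt/v),

with v² = σ̃₁²/n for the standard test and v² = (σ̃₁² − π(1−π)e²)/n for the
augmented test, where

σ̃₁² = {π(1−π)}⁻¹ ∫₀^τ {∫ₜ^τ S₀ du}² / {S₀(t)G(t)} dΛ₀(t)

needs only the control survival law S₀ and the common censoring law G, and
e² is a quadratic form between martingale-residual integrals and the
covariates that can be estimated from control-only reference data — or,
mid-trial, from pooled blinded data, since none of these quantities involves
the treatment assignment.

## Worked example

Design a trial to detect an RMST difference of 150 days at τ = 1825 days
(5 years), assuming exponential survival and censoring laws matched to a
5-year survival of 0.520 and a 5-year censoring-free probability of 0.965:

```r
library(rmstaug)

lamS <- exp_rate_from_survival(0.520, 1825)   # 3.583e-04
lamG <- exp_rate_from_survival(0.965, 1825)   # 1.952e-05
s2 <- sigma_tilde_sq(dist_exponential(lamS), dist_exponential(lamG),
                     tau = 1825)
predicted_power(150, n = 490, sigma_tilde_sq = s2)
#> # A tibble: 1 x 9
#>   theta_alt     n sigma_tilde_sq  e_sq    q2     v v_aug power_standard power_augmented
#>       <dbl> <int>          <dbl> <dbl> <dbl> <dbl> <dbl>          <dbl>           <dbl>
#> 1       150   490       1556427.     0     0  56.4  56.4          0.759           0.759
```

A predicted power of 0.759: the exponential approximation is noticeably
below the 0.8 target that the same design reaches when S₀ and G are
estimated from reference data — the shape of the survival curve matters.

Analysis side, on simulated data with two prognostic covariates:

```r
d <- sim_trial("2a", n = 400, seed = 3)        # PH alternative, copula covariates
rmst_test(d, tau = 5)
#> standard RMST difference test (tau = 5, n = 400)
#>   RMST treatment 3.136, control 2.586, difference 0.5502 (SE 0.1938)
#>   95% CI (0.1702, 0.9301), z = 2.838, p = 0.004538
rmst_augmented_test(d, tau = 5, covariates = c("v1", "v2"))
#> augmented RMST difference test (tau = 5, n = 400)
#>   RMST treatment 3.136, control 2.586, difference 0.4573 (SE 0.1671)
#>   95% CI (0.1298, 0.7848), z = 2.737, p = 0.006209
#>   augmentation: v1 = -2.014, v2 = -2.003; var. reduction 15.03 -> 11.17
```

The augmentation cuts the squared standard error by about a quarter here —
the same subjects, a shorter confidence interval.

Mid-trial, with a blinded 200-subject snapshot (no arm column!):

```r
snap <- sim_trial("2a", 200, seed = 9)[c("time", "event", "v1", "v2")]
reestimate_n(snap, tau = 5, theta_alt = 0.514, test = "augmented",
             covariates = c("v1", "v2"))
#> Blinded sample-size re-estimation (augmented test)
#>   n_mid = 200, sigma_tilde_sq = 15.09, e_sq = 17.29
#>   n_final = 320 with predicted power 0.8001 (target 0.800 at theta_alt = 0.514)
```

`tidy()`/`glance()` methods return tibbles for all fitted objects, and
`autoplot()` draws the survival curves or the power-versus-n scan. A thin
command-line wrapper (`inst/cli/rmstaug`) exposes the same operations as
subcommands (`test`, `augtest`, `power`, `samplesize`, `reestimate`,
`select-covariates`, `simulate`, `run-study`) on CSV/TSV files.

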