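# Scenario generators for the operating-characteristics study: exponential or
# piecewise-exponential marginals with 5-year control survival 0.2, a Gaussian
# copula linking the failure time to two continuous baseline covariates
# (setting "a") or not (setting "b"), and Uniform(0, 8) administrative
# censoring, evaluated at tau = 5.

.scenario_ids <- c("1a", "1b", "2a", "2b", "3a", "3b")

#' Simulation scenario parameters
#'
#' Resolves one of the six built-in scenarios.  The control arm is always
#' exponential with rate `lambda0 = -log(0.2)/5` (5-year survival 0.2).
#' Scenarios `1a`/`1b` are null (hazard ratio 1); `2a`/`2b` are proportional
#' hazards with ratio 0.7; `3a`/`3b` are non-proportional: the treatment
#' hazard equals `lambda0` before `t = 1` and a solved `lambda2` after, such
#' that the true RMST difference over `[0, 5]` equals that of scenario 2.
#' Suffix `a` means the failure time depends on the covariates `v1`, `v2`
#' through the copula `U = Phi_3(b1 + b2 + eps)`; suffix `b` uses
#' `U = Phi_1(eps)`, independent of the covariates.
#'
#' @param id Scenario id: `"1a"`, `"1b"`, `"2a"`, `"2b"`, `"3a"` or `"3b"`
#'   (a `"sData"` prefix is tolerated).
#' @return A list of class `sim_scenario` with the resolved parameters:
#'   `id`, `lambda0`, `hazard_ratio`, `lambda2` (scenario 3), `change_time`,
#'   `tau`, `censor_upper`, `copula`, `pi`.
#' @export
sim_scenario <- function(id) {
  if (inherits(id, "sim_scenario")) return(id)
  id <- sub("^sData\\s*", "", as.character(id))
  if (!id %in% .scenario_ids) {
    abort(sprintf("unknown scenario id '%s' (expected one of %s)",
                  id, paste(.scenario_ids, collapse = ", ")))
  }
  lambda0 <- -log(0.2) / 5
  family <- substr(id, 1, 1)
  hr <- switch(family, "1" = 1, "2" = 0.7, "3" = NA_real_)
  lambda2 <- if (family == "3") {
    solve_lambda2(lambda0, change_time = 1, tau = 5,
                  target_diff = .rmst_exp(0.7 * lambda0, 5) - .rmst_exp(lambda0, 5))
  } else NA_real_
  structure(list(id = id, family = family, lambda0 = lambda0,
                 hazard_ratio = hr, lambda2 = lambda2, change_time = 1,
                 tau = 5, censor_upper = 8,
                 copula = substr(id, 2, 2), pi = 0.5),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario %s: lambda0 = %.4f, %s, copula %s>\n", x$id,
              x$lambda0,
              switch(x$family,
                     "1" = "null",
                     "2" = sprintf("PH hazard ratio %.2f", x$hazard_ratio),
                     "3" = sprintf("non-PH lambda2 = %.4f after t = %g",
                                   x$lambda2, x$change_time)),
              x$copula))
  invisible(x)
}

.rmst_exp <- function(rate, tau) (1 - exp(-rate * tau)) / rate

.rmst_pwexp2 <- function(lambda0, lambda2, change_time, tau) {
  (1 - exp(-lambda0 * change_time)) / lambda0 +
    exp(-lambda0 * change_time) *
      (1 - exp(-lambda2 * (tau - change_time))) / lambda2
}

#' Solve the post-change hazard for a target RMST difference
#'
#' Finds `lambda2` such that the piecewise-exponential treatment law (hazard
#' `lambda0` before `change_time`, `lambda2` after) beats the exponential
#' control law (rate `lambda0`) by `target_diff` in RMST over `[0, tau]`.
#'
#' @param lambda0 Control hazard rate.
#' @param change_time Hazard change point.
#' @param tau Truncation time.
#' @param target_diff Target RMST difference (time units).
#' @return `lambda2`, solved to an RMST-difference residual below 1e-10.
#' @export
solve_lambda2 <- function(lambda0, change_time = 1, tau = 5, target_diff) {
  r0 <- .rmst_exp(lambda0, tau)
  max_diff <- (1 - exp(-lambda0 * change_time)) / lambda0 +
    exp(-lambda0 * change_time) * (tau - change_time) - r0
  if (target_diff >= max_diff - 1e-12 || target_diff <= -r0 +
        (1 - exp(-lambda0 * change_time)) / lambda0) {
    abort(sprintf("target_diff %.4g not achievable (feasible range is about (%.4g, %.4g))",
                  target_diff,
                  (1 - exp(-lambda0 * change_time)) / lambda0 - r0, max_diff))
  }
  f <- function(l2) .rmst_pwexp2(lambda0, l2, change_time, tau) - r0 - target_diff
  upper <- lambda0
  while (f(upper) > 0) upper <- upper * 2   # target_diff < 0 pushes lambda2 up
  uniroot(f, c(1e-12, upper), tol = 1e-14)$root
}

#' True RMST difference of a scenario
#'
#' Closed-form `int_0^tau {S1(t) - S0(t)} dt` under the scenario's marginal
#' laws: 0 for the null scenarios, `(5/log 5) {(1 - 0.2^0.7)/0.7 - 0.8}`
#' (about 0.514) for the proportional-hazards and, by construction of
#' `lambda2`, also for the non-proportional scenarios.
#'
#' @param scenario A scenario id or `sim_scenario`.
#' @return The difference, in time units.
#' @examples
#' true_rmst_diff("2a")
#' @export
true_rmst_diff <- function(scenario) {
  sc <- sim_scenario(scenario)
  switch(sc$family,
    "1" = 0,
    "2" = .rmst_exp(sc$hazard_ratio * sc$lambda0, sc$tau) -
      .rmst_exp(sc$lambda0, sc$tau),
    "3" = .rmst_pwexp2(sc$lambda0, sc$lambda2, sc$change_time, sc$tau) -
      .rmst_exp(sc$lambda0, sc$tau)
  )
}

# Fast vector generator used by sim_trial() and the study harness.  Draw
# order is fixed (b1, b2, eps1, eps2, eps, Z, C) so a seed pins the dataset.
.sim_vectors <- function(sc, n) {
  b1 <- rnorm(n); b2 <- rnorm(n)
  e1 <- rnorm(n); e2 <- rnorm(n); eps <- rnorm(n)
  u <- if (sc$copula == "a") pnorm(b1 + b2 + eps, sd = sqrt(3)) else pnorm(eps)
  z <- rbinom(n, 1L, sc$pi)
  E <- -log(u)                      # unit-exponential via inverse CDF
  t0 <- E / sc$lambda0
  t1 <- switch(sc$family,
    "1" = t0,
    "2" = E / (sc$hazard_ratio * sc$lambda0),
    "3" = {
      thr <- sc$lambda0 * sc$change_time
      ifelse(E < thr, E / sc$lambda0,
             sc$change_time + (E - thr) / sc$lambda2)
    })
  tt <- ifelse(z == 1L, t1, t0)
  cc <- runif(n, 0, sc$censor_upper)
  list(time = pmin(tt, cc), event = as.integer(tt <= cc), arm = z,
       v1 = b1 + e1, v2 = b2 + e2)
}

.sim_control_vectors <- function(sc, n) {
  b1 <- rnorm(n); b2 <- rnorm(n)
  e1 <- rnorm(n); e2 <- rnorm(n); eps <- rnorm(n)
  u <- if (sc$copula == "a") pnorm(b1 + b2 + eps, sd = sqrt(3)) else pnorm(eps)
  tt <- -log(u) / sc$lambda0
  cc <- runif(n, 0, sc$censor_upper)
  list(time = pmin(tt, cc), event = as.integer(tt <= cc),
       v1 = b1 + e1, v2 = b2 + e2)
}

#' Simulate a randomized trial
#'
#' Generates `n` subjects under a built-in scenario: standard-normal latents
#' `b1, b2, eps1, eps2, eps`; covariates `v1 = b1 + eps1`,
#' `v2 = b2 + eps2` (each marginally N(0, 2)); copula variable
#' `U = Phi_3(b1 + b2 + eps)` (setting `a`, failure time depends on the
#' covariates) or `U = Phi_1(eps)` (setting `b`); equal randomization
#' `Z ~ Bernoulli(1/2)` independent of the covariates; failure time by the
#' inverse CDF of the arm's marginal law applied through `-log(U)`;
#' independent `C ~ Uniform(0, 8)` censoring.  Deterministic given `seed`.
#'
#' @param scenario Scenario id or `sim_scenario`.
#' @param n Number of subjects (>= 2).
#' @param seed Optional integer seed.
#' @return A tibble with columns `id`, `time`, `event`, `arm`, `v1`, `v2`.
#' @examples
#' sim_trial("1a", n = 6, seed = 1)
#' @export
sim_trial <- function(scenario, n, seed = NULL) {
  sc <- sim_scenario(scenario)
  if (n < 2) abort("n must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  v <- .sim_vectors(sc, n)
  tibble(id = seq_len(n), time = v$time, event = v$event, arm = v$arm,
         v1 = v$v1, v2 = v$v2)
}

#' Simulate a control-only reference dataset
#'
#' Draws subjects from the scenario's control law only (`arm` fixed at 0).
#' `matched = FALSE` gives the covariate-truncated ("mis-matched") variant:
#' rejection sampling keeps only subjects with `v1 < 1` and `v2 < 1`, a
#' biased sample of the control population.
#'
#' @inheritParams sim_trial
#' @param n_ref Number of reference subjects.
#' @param matched Sample the control law directly (`TRUE`) or the truncated
#'   variant (`FALSE`)?
#' @return A tibble with columns `id`, `time`, `event`, `arm` (all 0),
#'   `v1`, `v2`.
#' @export
sim_reference <- function(scenario, n_ref, matched = TRUE, seed = NULL) {
  sc <- sim_scenario(scenario)
  if (n_ref < 2) abort("n_ref must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  if (matched) {
    v <- .sim_control_vectors(sc, n_ref)
  } else {
    acc <- list(time = numeric(0), event = integer(0),
                v1 = numeric(0), v2 = numeric(0))
    while (length(acc$time) < n_ref) {
      cand <- .sim_control_vectors(sc, 4L * n_ref)
      keep <- cand$v1 < 1 & cand$v2 < 1
      acc <- Map(c, acc, lapply(cand, `[`, keep))
    }
    v <- lapply(acc, head, n_ref)
  }
  tibble(id = seq_len(n_ref), time = v$time, event = v$event,
         arm = 0L, v1 = v$v1, v2 = v$v2)
}
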