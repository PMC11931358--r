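#' Survival / censoring distribution specifications
#'
#' Lightweight specs for the two laws entering the local power formula: the
#' control-arm survival function `S0` and the common censoring survival
#' function `G`.  Parametric specs (`dist_exponential()`,
#' `dist_piecewise_exponential()`, `dist_uniform()`) are evaluated in closed
#' form; `dist_km()` wraps a fitted [km_curve()] (forward or reverse) so that
#' all integrals are exact step sums.
#'
#' @param rate Exponential hazard rate (> 0).
#' @param rates Piecewise-exponential hazard rates, one per interval.
#' @param cutpoints Increasing interior change points
#'   (length `length(rates) - 1`).
#' @param upper Upper bound of a `Uniform(0, upper)` law (used for
#'   administrative censoring).
#' @param curve An `rmst_curve` from [km_curve()].
#' @return An object of class `dist_spec`.
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_exponential <- function(rate) {
  if (!is.numeric(rate) || rate <= 0) abort("rate must be > 0")
  structure(list(kind = "exponential", rate = rate), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_piecewise_exponential <- function(rates, cutpoints) {
  if (any(rates <= 0)) abort("rates must be > 0")
  if (length(cutpoints) != length(rates) - 1L) {
    abort("need one cutpoint fewer than rates")
  }
  if (is.unsorted(cutpoints, strictly = TRUE) || any(cutpoints <= 0)) {
    abort("cutpoints must be positive and strictly increasing")
  }
  structure(list(kind = "piecewise_exponential", rates = rates,
                 cutpoints = cutpoints), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(upper) {
  if (upper <= 0) abort("upper must be > 0")
  structure(list(kind = "uniform", upper = upper), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_km <- function(curve) {
  if (!inherits(curve, "rmst_curve")) abort("curve must be an rmst_curve")
  if (attr(curve, "type") == "cumhaz") abort("need a survival-type curve")
  structure(list(kind = "km", curve = curve), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec:", x$kind, ">\n")
  invisible(x)
}

# survival function of a spec, vectorized (right-continuous for km)
.spec_surv <- function(spec, t, left = FALSE) {
  switch(spec$kind,
    exponential = exp(-spec$rate * t),
    piecewise_exponential = exp(-.pwexp_cumhaz(spec, t)),
    uniform = pmax(0, 1 - t / spec$upper),
    km = curve_value(spec$curve, t, left = left),
    abort("unknown distribution kind")
  )
}

.pwexp_cumhaz <- function(spec, t) {
  brk <- c(0, spec$cutpoints)
  j <- findInterval(t, brk)
  # cumulative hazard accrued up to the start of each interval
  start <- c(0, cumsum(spec$rates[-length(spec$rates)] *
                         diff(c(0, spec$cutpoints))))
  start[j] + spec$rates[j] * (t - brk[j])
}

# int_t^tau S(u) du for a spec, vectorized over t (0 <= t <= tau)
.spec_tail <- function(spec, t, tau) {
  switch(spec$kind,
    exponential = (exp(-spec$rate * t) - exp(-spec$rate * tau)) / spec$rate,
    uniform = {
      b <- spec$upper
      hi <- pmin(tau, b)
      lo <- pmin(t, b)
      (hi - lo) - (hi^2 - lo^2) / (2 * b)
    },
    piecewise_exponential = vapply(t, function(tt) {
      brk <- sort(unique(c(tt, spec$cutpoints[spec$cutpoints > tt &
                                                spec$cutpoints < tau], tau)))
      tot <- 0
      for (j in seq_len(length(brk) - 1L)) {
        a <- brk[j]; b <- brk[j + 1L]
        r <- spec$rates[findInterval(a, c(0, spec$cutpoints))]
        tot <- tot + (exp(-.pwexp_cumhaz(spec, a)) -
                        exp(-.pwexp_cumhaz(spec, b))) / r
      }
      tot
    }, numeric(1)),
    km = abort("use step sums for km specs"),
    abort("unknown distribution kind")
  )
}

.spec_hazard <- function(spec, t) {
  switch(spec$kind,
    exponential = rep(spec$rate, length(t)),
    piecewise_exponential = spec$rates[findInterval(t, c(0, spec$cutpoints))],
    uniform = 1 / (spec$upper - t),
    abort("no continuous hazard for this kind")
  )
}

#' Exponential rate matching a survival probability
#'
#' The hazard of the exponential law whose survival at time `t` equals `p`:
#' `rate = -log(p) / t`.
#'
#' @param p Survival probability at `t`, in (0, 1).
#' @param t Time (> 0).
#' @return The rate, in inverse time units.
#' @examples
#' exp_rate_from_survival(0.520, 1825)
#' @export
exp_rate_from_survival <- function(p, t) {
  if (any(p <= 0 | p >= 1)) abort("p must be in (0, 1)")
  if (any(t <= 0)) abort("t must be > 0")
  -log(p) / t
}

#' Local-power variance of the RMST difference
#'
#' The null-approximated variance of `sqrt(n)` times the RMST-difference
#' estimator,
#' `sigma_tilde^2 = {pi(1-pi)}^-1 int_0^tau {int_t^tau S0}^2 / {S0(t) G(t)} dLambda0(t)`,
#' which depends only on the control survival law `S0` and the common
#' censoring law `G`.  Step-curve specs are integrated exactly; parametric
#' specs by adaptive quadrature (relative tolerance 1e-8).
#'
#' @param s0 A [dist_spec] for the control survival function.
#' @param g A [dist_spec] for the censoring survival function.
#' @param tau Truncation time.
#' @param pi Allocation probability.
#' @param extend Follow-up support policy for step curves.
#' @return The variance, in squared time units.
#' @examples
#' sigma_tilde_sq(dist_exponential(log(5) / 5), dist_uniform(8), tau = 5)
#' @export
sigma_tilde_sq <- function(s0, g, tau, pi = 0.5,
                           extend = c("flat", "quiet", "error")) {
  extend <- match.arg(extend)
  if (pi <= 0 || pi >= 1) abort("pi must be in (0, 1)")
  if (s0$kind == "km") {
    crv <- s0$curve
    if (extend != "quiet") .check_support(attr(crv, "max_followup"), tau, "S0 curve", extend)
    keep <- crv$time <= tau
    tk <- crv$time[keep]
    if (!length(tk)) {
      warn("S0 has no event mass on [0, tau]; sigma_tilde_sq is 0")
      return(0)
    }
    dLam <- (crv$n.event / crv$n.risk)[keep]
    S <- crv$estimate[keep]
    K <- length(tk)
    seg <- c(if (K > 1) diff(tk) * S[-K], (tau - tk[K]) * S[K])
    area <- rev(cumsum(rev(seg)))
    S_left <- c(1, S[-K])
    G_left <- .spec_surv(g, tk, left = TRUE)
    if (any(G_left <= 0)) abort("censoring support ends before an event time within [0, tau]")
    sum(area^2 * dLam / (S_left * G_left)) / (pi * (1 - pi))
  } else {
    if (g$kind == "uniform" && g$upper <= tau) {
      abort("uniform censoring upper bound must exceed tau")
    }
    f <- function(t) {
      .spec_tail(s0, t, tau)^2 * .spec_hazard(s0, t) /
        (.spec_surv(s0, t) * .spec_surv(g, t, left = TRUE))
    }
    integrate(f, 0, tau, rel.tol = 1e-8)$value / (pi * (1 - pi))
  }
}

#' Covariate variance reduction e-squared from reference data
#'
#' The variance explained by the covariate augmentation, estimated from a
#' single-group (control-only or pooled blinded) dataset as the quadratic
#' form between the per-subject martingale-residual integrals
#' `g_i = int_0^tau {int_t^tau S0_hat du / Ybar(t)} dM_hat_i(t)` and the
#' covariates:
#' `e_hat^2 = {pi(1-pi)}^-2 (1/n) a' B^-1 a` with `a = sum g_i V_i`,
#' `B = sum V_i V_i'`.  The augmented local-power variance is then
#' `sigma_tilde^2 - pi(1-pi) e_hat^2`.  Always nonnegative; exactly zero for
#' a constant covariate because the residual increments sum to zero at every
#' event time.
#'
#' @param data A single-group survival data frame: either without an `arm`
#'   column, or with `arm` identically 0 (a control-only reference set).
#'   Set `pooled = TRUE` to ignore a present `arm` column (blinded data).
#' @param tau Truncation time.
#' @param covariates Covariate column names; `NULL` uses every numeric column
#'   outside the core schema.
#' @param pi Allocation probability of the trial being designed.
#' @param pooled Ignore the `arm` column?
#' @param extend Follow-up support policy.
#' @return `e_hat^2`, in squared time units.
#' @export
e_squared <- function(data, tau, covariates = NULL, pi = 0.5, pooled = FALSE,
                      extend = c("flat", "quiet", "error")) {
  extend <- match.arg(extend)
  covariates <- covariates %||% .default_covariates(data)
  if (!length(covariates)) abort("at least one covariate is required")
  data <- check_survival_data(data, covariates = covariates, require_arm = FALSE)
  if ("arm" %in% names(data) && !pooled && any(data$arm != 0)) {
    abort("reference data must be control-only (arm == 0); use pooled = TRUE for blinded data")
  }
  V <- .cov_matrix(data, covariates)
  if (nrow(data) < ncol(V) + 2L) abort("too few subjects for the covariate count")
  .pooled_inputs(data$time, data$event, V, tau, pi = pi, extend = extend,
                 label = "reference data")$e_sq
}

#' Local power of the standard and augmented RMST tests
#'
#' Two-sided local asymptotic power
#' `Phi(z_{alpha/2} - theta_alt / v) + 1 - Phi(z_{1-alpha/2} - theta_alt / v)`
#' with `v^2 = sigma_tilde^2 / n` for the standard test and
#' `v_aug^2 = {sigma_tilde^2 - pi(1-pi) e_sq} / n` for the augmented test.
#' At `theta_alt = 0` both powers equal `alpha` exactly.
#'
#' @param theta_alt Alternative RMST difference (time units).
#' @param n Total sample size(s); may be a vector.
#' @param sigma_tilde_sq Local-power variance, from [sigma_tilde_sq()] or
#'   reference/blinded data.
#' @param e_sq Covariate variance reduction; 0 for the standard test only.
#' @param alpha Two-sided significance level.
#' @param pi Allocation probability.  The augmented formula is derived for
#'   equal allocation, so `e_sq > 0` with `pi != 1/2` is an error.
#' @return A tibble with one row per `n`: `theta_alt`, `n`,
#'   `sigma_tilde_sq`, `e_sq`, `q2 = pi(1-pi) e_sq`, `v`, `v_aug`,
#'   `power_standard`, `power_augmented`.
#' @examples
#' s2 <- sigma_tilde_sq(dist_exponential(log(5) / 5), dist_uniform(8), 5)
#' predicted_power(0.514, n = 500, sigma_tilde_sq = s2)
#' @export
predicted_power <- function(theta_alt, n, sigma_tilde_sq, e_sq = 0,
                            alpha = 0.05, pi = 0.5) {
  if (any(n < 2)) abort("n must be at least 2")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (e_sq < 0) abort("e_sq must be nonnegative")
  if (e_sq > 0 && abs(pi - 0.5) > 1e-12) {
    abort("augmented local power is derived for equal allocation (pi = 1/2)")
  }
  q2 <- pi * (1 - pi) * e_sq
  if (q2 >= sigma_tilde_sq) abort("augmentation variance exceeds total")
  v <- sqrt(sigma_tilde_sq / n)
  v_aug <- sqrt((sigma_tilde_sq - q2) / n)
  tibble(
    theta_alt = theta_alt, n = as.integer(n),
    sigma_tilde_sq = sigma_tilde_sq, e_sq = e_sq, q2 = q2,
    v = v, v_aug = v_aug,
    power_standard = .local_power(theta_alt, v, alpha),
    power_augmented = .local_power(theta_alt, v_aug, alpha)
  )
}

#' Required sample size on a grid
#'
#' Smallest `n` on the grid `n_min, n_min + step, ...` whose predicted local
#' power reaches the target.
#'
#' @inheritParams predicted_power
#' @param target_power Target power, in `(alpha, 1)`.
#' @param test Which test's power must reach the target.
#' @param n_min,n_max,step Search grid.
#' @return An object of class `rmst_samplesize`: list with `n`, `power`
#'   (power at the chosen `n`), `test`, and `table`, the tibble of the grid
#'   scan from [predicted_power()].
#' @export
required_n <- function(theta_alt, sigma_tilde_sq, e_sq = 0, target_power = 0.8,
                       test = c("standard", "augmented"), alpha = 0.05,
                       pi = 0.5, n_min = 10, n_max = 10000, step = 10) {
  test <- match.arg(test)
  if (target_power <= alpha || target_power >= 1) {
    abort("target_power must be in (alpha, 1)")
  }
  if (theta_alt == 0) abort("theta_alt must be nonzero for sizing")
  if (step < 1) abort("step must be at least 1")
  grid <- seq(n_min, n_max, by = step)
  tab <- predicted_power(theta_alt, grid, sigma_tilde_sq, e_sq,
                         alpha = alpha, pi = pi)
  pw <- if (test == "standard") tab$power_standard else tab$power_augmented
  hit <- which(pw >= target_power)
  if (!length(hit)) {
    abort(sprintf("target power %.3f not reached by n_max = %d (power there %.4f)",
                  target_power, max(grid), pw[length(pw)]))
  }
  structure(list(n = grid[hit[1]], power = pw[hit[1]], test = test,
                 target_power = target_power, theta_alt = theta_alt,
                 alpha = alpha, pi = pi, table = tab),
            class = "rmst_samplesize")
}

#' @export
print.rmst_samplesize <- function(x, ...) {
  cat(sprintf("Required n = %d (%s test): predicted power %.4f >= target %.3f at theta_alt = %g\n",
              x$n, x$test, x$power, x$target_power, x$theta_alt))
  invisible(x)
}

#' @rdname required_n
#' @param x An `rmst_samplesize` object.
#' @param ... Unused.
#' @export
tidy.rmst_samplesize <- function(x, ...) x$table

#' @rdname required_n
#' @export
glance.rmst_samplesize <- function(x, ...) {
  tibble(n = x$n, power = x$power, test = x$test,
         target_power = x$target_power, theta_alt = x$theta_alt,
         alpha = x$alpha)
}

#' Design-stage predicted power from reference data
#'
#' Estimates `S0` (Kaplan-Meier), `G` (reverse Kaplan-Meier, unless a
#' parametric spec is supplied) and, when covariates are given, `e^2` from a
#' control-only reference dataset, then evaluates the local power of the
#' standard and augmented tests at the supplied sample size(s).
#'
#' @inheritParams e_squared
#' @param theta_alt Alternative RMST difference to detect.
#' @param n Sample size(s) of the trial being designed; may be a vector.
#' @param alpha Two-sided significance level.
#' @param g Optional [dist_spec] for the censoring law; `NULL` estimates it
#'   from the reference data by reverse Kaplan-Meier.
#' @return The [predicted_power()] tibble, with attributes `s0`, `g`
#'   (the fitted curves) and `n_ref`.
#' @examples
#' ref <- sim_reference("2a", n_ref = 200, seed = 3)
#' design_power(ref, tau = 5, theta_alt = 0.514, n = 500,
#'              covariates = c("v1", "v2"))
#' @export
design_power <- function(data, tau, theta_alt, n, covariates = NULL,
                         alpha = 0.05, pi = 0.5, g = NULL, pooled = FALSE,
                         extend = c("flat", "quiet", "error")) {
  extend <- match.arg(extend)
  data <- check_survival_data(data, covariates = covariates, require_arm = FALSE)
  if ("arm" %in% names(data) && !pooled && any(data$arm != 0)) {
    abort("reference data must be control-only (arm == 0); use pooled = TRUE for blinded data")
  }
  s0 <- km_curve(data)
  gspec <- g %||% dist_km(km_curve(data, reverse = TRUE))
  V <- .cov_matrix(data, covariates)
  inp <- .pooled_inputs(data$time, data$event, V, tau, pi = pi,
                        extend = extend, label = "reference data")
  # when the censoring law is supplied rather than estimated, the score-form
  # plug-in (which carries the data's own censoring) is replaced by the
  # curve-based integral against the supplied G
  sts <- if (is.null(g)) inp$sigma_tilde_sq else {
    sigma_tilde_sq(dist_km(s0), gspec, tau, pi = pi, extend = "quiet")
  }
  out <- predicted_power(theta_alt, n, sts, inp$e_sq, alpha = alpha, pi = pi)
  attr(out, "s0") <- s0
  attr(out, "g") <- gspec
  attr(out, "n_ref") <- nrow(data)
  out
}

#' Stepwise forward covariate selection by e-squared gain
#'
#' Greedy forward path: the first stage selects the single candidate with the
#' largest `e^2`; each later stage adds the candidate giving the largest gain
#' in `e^2`, until all candidates are included.  `e^2` never decreases along
#' the path (nested projections), so where to stop ("saturation") is left to
#' the caller; supplying `n` and `theta_alt` adds the augmented predicted
#' power per stage to make the cut explicit.
#'
#' @inheritParams e_squared
#' @param candidates Candidate covariate column names; `NULL` uses every
#'   numeric column outside the core schema.
#' @param n,theta_alt Optional sample size and alternative for a per-stage
#'   predicted-power column.
#' @param alpha Two-sided significance level for the power column.
#' @return A tibble with one row per stage: `step`, `variable`, `e_sq`
#'   (after adding the variable), `gain`, and `power_augmented` when `n` and
#'   `theta_alt` are given.  Candidates collinear with the selected set are
#'   skipped with a warning.
#' @export
stepwise_covariates <- function(data, tau, candidates = NULL, pi = 0.5,
                                n = NULL, theta_alt = NULL, alpha = 0.05,
                                pooled = FALSE,
                                extend = c("flat", "quiet", "error")) {
  extend <- match.arg(extend)
  candidates <- candidates %||% .default_covariates(data)
  if (!length(candidates)) abort("at least one candidate is required")
  data <- check_survival_data(data, covariates = candidates, require_arm = FALSE)
  if ("arm" %in% names(data) && !pooled && any(data$arm != 0)) {
    abort("reference data must be control-only (arm == 0); use pooled = TRUE for blinded data")
  }
  V_all <- .cov_matrix(data, candidates)
  np <- nrow(data)
  st <- .arm_stats(data$time, data$event, np, tau)
  .check_support(st$max_followup, tau, "reference data", extend)
  gscore <- .arm_scores(data$time, data$event, st, tau)
  scale <- 1 / (pi * (1 - pi))^2
  e2_of <- function(cols) {
    V <- V_all[, cols, drop = FALSE]
    B <- crossprod(V)
    if (qr(B)$rank < ncol(V)) return(NA_real_)
    a <- crossprod(V, gscore)
    scale * drop(crossprod(a, solve(B, a))) / np
  }
  sts <- if (!is.null(n)) mean(gscore^2) / (pi * (1 - pi)) else NA_real_
  selected <- character(0)
  rows <- list()
  remaining <- candidates
  prev <- 0
  step_i <- 1L
  while (length(remaining)) {
    vals <- vapply(remaining, function(v) e2_of(c(selected, v)), numeric(1))
    if (all(is.na(vals))) {
      warn(sprintf("skipping collinear candidate(s): %s",
                   paste(remaining, collapse = ", ")))
      break
    }
    if (anyNA(vals)) {
      warn(sprintf("skipping collinear candidate(s): %s",
                   paste(remaining[is.na(vals)], collapse = ", ")))
      remaining <- remaining[!is.na(vals)]
      vals <- vals[!is.na(vals)]
    }
    best <- which.max(vals)
    pick <- remaining[best]
    selected <- c(selected, pick)
    rows[[step_i]] <- tibble(
      step = step_i, variable = pick, e_sq = unname(vals[best]),
      gain = unname(vals[best]) - prev,
      power_augmented = if (!is.null(n) && !is.null(theta_alt)) {
        predicted_power(theta_alt, n, sts, vals[best], alpha = alpha,
                        pi = pi)$power_augmented
      } else NA_real_
    )
    prev <- vals[best]
    remaining <- remaining[-best]
    step_i <- step_i + 1L
  }
  bind_rows(rows)
}
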