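#' Blinded design inputs from pooled mid-trial data
#'
#' Estimates the quantities the local power formula needs from a
#' treatment-blinded snapshot: `S0` by Kaplan-Meier on the pooled sample,
#' `G` by reverse Kaplan-Meier, and (when covariates are supplied) `e^2`
#' with all martingale residuals taken under the pooled Nelson-Aalen
#' estimate, i.e. under the null.  None of these quantities uses the
#' treatment assignment, which is what makes the mid-trial review blinded.
#'
#' To enforce blindness the input must not carry an `arm` column; passing
#' data that still has one is an error unless `strip_arm = TRUE` explicitly
#' discards it.
#'
#' @param data Pooled survival data frame (`time`, `event`, covariates;
#'   no `arm`).
#' @param tau Truncation time; every subject in the snapshot must have
#'   follow-up resolved up to `tau`.
#' @param covariates Covariate column names, required if the augmented test
#'   is planned; `NULL` for the standard test.
#' @param pi Allocation probability of the trial.
#' @param strip_arm Discard an `arm` column instead of erroring?
#' @param extend Follow-up support policy (a pooled support shorter than
#'   `tau` triggers the flat-extension warning prominently).
#' @return A list: `s0` and `g` (fitted `rmst_curve`s), `sigma_tilde_sq`,
#'   `e_sq`, `n_mid`.
#' @export
blinded_inputs <- function(data, tau, covariates = NULL, pi = 0.5,
                           strip_arm = FALSE,
                           extend = c("flat", "quiet", "error")) {
  extend <- match.arg(extend)
  if ("arm" %in% names(data)) {
    if (!strip_arm) {
      abort("blinded data must not contain an 'arm' column (set strip_arm = TRUE to discard it)")
    }
    data <- data[setdiff(names(data), "arm")]
  }
  data <- check_survival_data(data, covariates = covariates, require_arm = FALSE)
  V <- .cov_matrix(data, covariates)
  inp <- .pooled_inputs(data$time, data$event, V, tau, pi = pi,
                        extend = extend, label = "pooled blinded data")
  list(s0 = km_curve(data), g = km_curve(data, reverse = TRUE),
       sigma_tilde_sq = inp$sigma_tilde_sq, e_sq = inp$e_sq, n_mid = inp$n)
}

#' Blinded mid-trial sample-size re-estimation
#'
#' Recomputes the required sample size from a pooled, treatment-blinded
#' snapshot of `n_mid` subjects followed to `tau`: estimates the local-power
#' inputs with [blinded_inputs()], scans `n = n_mid, n_mid + step, ...` and
#' returns the first `n` whose predicted power (standard or augmented
#' formula) reaches the target.  The final size never drops below the
#' already-observed `n_mid`.
#'
#' @inheritParams blinded_inputs
#' @param theta_alt Target RMST difference the trial must detect.
#' @param target_power Target power.
#' @param test Which test the trial will use; `"augmented"` requires
#'   covariates.
#' @param alpha Two-sided significance level.
#' @param step,n_max Search grid above `n_mid`.
#' @return An object of class `rmst_reestimate`: list with `n_mid`,
#'   `n_final`, the selected test's `power` at `n_final`, the blinded
#'   `inputs`, and `table` with all intermediate powers.  Methods:
#'   [tidy()], [glance()], `print()`, [ggplot2::autoplot()].
#' @examples
#' d <- sim_trial("2a", n = 200, seed = 11)
#' reestimate_n(d[c("time", "event", "v1", "v2")], tau = 5,
#'              theta_alt = 0.514, test = "augmented",
#'              covariates = c("v1", "v2"))
#' @export
reestimate_n <- function(data, tau, theta_alt, target_power = 0.8,
                         test = c("standard", "augmented"), covariates = NULL,
                         alpha = 0.05, pi = 0.5, step = 10, n_max = 10000,
                         strip_arm = FALSE,
                         extend = c("flat", "quiet", "error")) {
  test <- match.arg(test)
  extend <- match.arg(extend)
  if (test == "augmented" && !length(covariates)) {
    abort("the augmented re-estimation needs covariates")
  }
  inp <- blinded_inputs(data, tau, covariates = covariates, pi = pi,
                        strip_arm = strip_arm, extend = extend)
  sel <- required_n(theta_alt, inp$sigma_tilde_sq,
                    e_sq = if (test == "augmented") inp$e_sq else 0,
                    target_power = target_power, test = test, alpha = alpha,
                    pi = pi, n_min = inp$n_mid, n_max = n_max, step = step)
  structure(list(
    n_mid = inp$n_mid, n_final = max(sel$n, inp$n_mid), power = sel$power,
    test = test, target_power = target_power, theta_alt = theta_alt,
    alpha = alpha, inputs = inp, table = sel$table
  ), class = "rmst_reestimate")
}

#' @export
print.rmst_reestimate <- function(x, ...) {
  cat(sprintf("Blinded sample-size re-estimation (%s test)\n", x$test))
  cat(sprintf("  n_mid = %d, sigma_tilde_sq = %.4g, e_sq = %.4g\n",
              x$n_mid, x$inputs$sigma_tilde_sq, x$inputs$e_sq))
  cat(sprintf("  n_final = %d with predicted power %.4f (target %.3f at theta_alt = %g)\n",
              x$n_final, x$power, x$target_power, x$theta_alt))
  invisible(x)
}

#' @rdname reestimate_n
#' @param x An `rmst_reestimate` object.
#' @param ... Unused.
#' @export
tidy.rmst_reestimate <- function(x, ...) x$table

#' @rdname reestimate_n
#' @export
glance.rmst_reestimate <- function(x, ...) {
  tibble(n_mid = x$n_mid, n_final = x$n_final, power = x$power,
         sigma_tilde_sq = x$inputs$sigma_tilde_sq, e_sq = x$inputs$e_sq,
         test = x$test, target_power = x$target_power,
         theta_alt = x$theta_alt, alpha = x$alpha)
}
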