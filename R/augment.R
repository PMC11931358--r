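#' Optimal augmentation coefficient
#'
#' Least-squares projection of the per-subject influence scores of the RMST
#' difference onto the span of the treatment-centered covariates
#' `(Z - pi) V`: `c_hat = {pi(1-pi) sum V_i V_i'}^-1 sum (Z_i - pi) V_i H_i`.
#' With equal allocation (`pi = 1/2`) this is exactly the empirical
#' least-squares minimizer of the augmented variance.
#'
#' @param data A two-arm survival data frame with numeric baseline covariates.
#' @param tau Truncation time.
#' @param covariates Covariate column names; `NULL` uses every numeric column
#'   outside the core schema.
#' @param pi Allocation probability `P(Z = 1)`.
#' @param allow_singular Use a pseudo-inverse for a singular covariate Gram
#'   matrix instead of erroring?  Collinear covariates are a design smell and
#'   the default is a hard error.
#' @param extend Follow-up support policy, see [curve_integral()].
#' @return Named numeric vector `c_hat` (units: time per covariate unit).
#' @export
augmentation_coefficient <- function(data, tau, covariates = NULL, pi = 0.5,
                                     allow_singular = FALSE,
                                     extend = c("flat", "quiet", "error")) {
  extend <- match.arg(extend)
  covariates <- covariates %||% .default_covariates(data)
  if (!length(covariates)) abort("at least one covariate is required")
  data <- check_survival_data(data, covariates = covariates, require_arm = TRUE)
  V <- .cov_matrix(data, covariates)
  fit <- .fit_rmst(data$time, data$event, data$arm, tau, extend = extend)
  .chat(fit$scores, data$arm, V, pi, allow_singular)
}

.chat <- function(H, arm, V, pi, allow_singular = FALSE) {
  A <- pi * (1 - pi) * crossprod(V)
  b <- crossprod(V, (arm - pi) * H)
  if (qr(A)$rank < ncol(V)) {
    if (!allow_singular) abort("collinear covariates")
    ch <- drop(MASS_ginv(A) %*% b)
  } else {
    ch <- drop(solve(A, b))
  }
  setNames(ch, colnames(V))
}

# Moore-Penrose pseudo-inverse via SVD (only used behind allow_singular).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Covariate-augmented RMST-difference test
#'
#' Subtracts the mean-zero augmentation term
#' `n^-1 sum (Z_i - pi) c_hat' V_i` from the standard RMST-difference
#' estimator and tests the difference with the augmented variance
#' `n^-1 sum {H_i - (Z_i - pi) c_hat' V_i}^2`.  Under randomization the
#' augmentation leaves the estimand untouched for any coefficient; the
#' projection coefficient of [augmentation_coefficient()] minimizes the
#' variance, so with `pi = 1/2` the augmented variance never exceeds the
#' score variance of the standard test.
#'
#' @inheritParams augmentation_coefficient
#' @param alpha Two-sided significance level.
#' @param coefficient Optional fixed coefficient vector to use instead of the
#'   estimated projection (e.g. `0` reproduces the standard test exactly).
#' @param standardize Rescale covariates by their standard deviations before
#'   solving, for numerical conditioning only; the estimate is invariant
#'   under any invertible linear reparameterization of the covariates, so
#'   this never changes the result beyond floating-point noise.
#' @return An object of class `rmst_aug_test` (inheriting `rmst_test`) with
#'   the augmented estimate, variance, test and the coefficient `c_hat`,
#'   plus the standard-test results in `$base`.
#' @examples
#' d <- sim_trial("2a", n = 300, seed = 7)
#' rmst_augmented_test(d, tau = 5, covariates = c("v1", "v2"))
#' @export
rmst_augmented_test <- function(data, tau, covariates = NULL, alpha = 0.05,
                                pi = 0.5, coefficient = NULL,
                                standardize = FALSE, allow_singular = FALSE,
                                extend = c("flat", "quiet", "error")) {
  extend <- match.arg(extend)
  if (pi <= 0 || pi >= 1) abort("pi must be in (0, 1)")
  covariates <- covariates %||% .default_covariates(data)
  if (!length(covariates)) abort("at least one covariate is required")
  data <- check_survival_data(data, covariates = covariates, require_arm = TRUE)
  V <- .cov_matrix(data, covariates)
  base <- rmst_test(data, tau, alpha = alpha, variance = "score", extend = extend)
  H <- base$scores
  if (is.null(coefficient)) {
    if (standardize) {
      sds <- apply(V, 2, sd)
      sds[sds == 0] <- 1
      ch <- .chat(H, data$arm, sweep(V, 2, sds, "/"), pi, allow_singular) / sds
    } else {
      ch <- .chat(H, data$arm, V, pi, allow_singular)
    }
  } else {
    ch <- setNames(rep_len(coefficient, ncol(V)), colnames(V))
  }
  adj <- (data$arm - pi) * drop(V %*% ch)
  estimate <- base$estimate - mean(adj)
  var_aug <- mean((H - adj)^2)
  if (var_aug <= 0) abort("no events within truncation window")
  se <- sqrt(var_aug / base$n)
  z <- estimate / se
  crit <- qnorm(1 - alpha / 2)
  structure(list(
    estimate = estimate, theta1 = base$theta1, theta0 = base$theta0,
    c_hat = ch, var_aug = var_aug,
    var_plugin = base$var_plugin, var_score = base$var_score,
    variance = "augmented", se = se, statistic = z,
    p.value = 2 * pnorm(-abs(z)),
    conf.low = estimate - crit * se, conf.high = estimate + crit * se,
    n = base$n, tau = tau, alpha = alpha, pi = pi,
    covariates = covariates, scores = H, base = base, curves = base$curves,
    method = "augmented RMST difference test"
  ), class = c("rmst_aug_test", "rmst_test"))
}

#' @export
print.rmst_aug_test <- function(x, digits = 4, ...) {
  NextMethod()
  cat(sprintf("  augmentation: %s; var. reduction %s -> %s\n",
              paste(sprintf("%s = %s", names(x$c_hat),
                            format(x$c_hat, digits = digits)), collapse = ", "),
              format(x$var_score, digits = digits),
              format(x$var_aug, digits = digits)))
  invisible(x)
}

#' @rdname rmst_augmented_test
#' @param x An `rmst_aug_test` object.
#' @param ... Unused.
#' @export
tidy.rmst_aug_test <- function(x, ...) {
  bind_rows(
    tibble(
      term = "rmst_difference_augmented", estimate = x$estimate,
      std.error = x$se, statistic = x$statistic, p.value = x$p.value,
      conf.low = x$conf.low, conf.high = x$conf.high
    ),
    tidy(x$base),
    tibble(term = paste0("c_hat_", names(x$c_hat)), estimate = unname(x$c_hat),
           std.error = NA_real_, statistic = NA_real_, p.value = NA_real_,
           conf.low = NA_real_, conf.high = NA_real_)
  )
}

#' @rdname rmst_augmented_test
#' @export
glance.rmst_aug_test <- function(x, ...) {
  tibble(n = x$n, tau = x$tau, estimate = x$estimate, std.error = x$se,
         statistic = x$statistic, p.value = x$p.value,
         var.augmented = x$var_aug, var.score = x$var_score,
         var.reduction = 1 - x$var_aug / x$var_score, method = x$method)
}
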