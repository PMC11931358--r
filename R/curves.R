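#' Kaplan-Meier (or reverse Kaplan-Meier) step curve
#'
#' Computes the product-limit estimate of the survival function, or of the
#' censoring distribution G when `reverse = TRUE` (censorings treated as
#' events; at tied times events leave the risk set before censorings).
#'
#' @param data A survival data frame with columns `time` and `event`
#'   (and `arm` when `arm` is requested).
#' @param arm `0`, `1` to fit one arm, or `NULL` to use all rows.
#' @param reverse Estimate the censoring distribution instead?
#' @return A tibble of class `rmst_curve` with one row per jump time and
#'   columns `time`, `n.risk`, `n.event`, `estimate`.  The origin value is 1
#'   and the curve is right-continuous.  Attributes `n`, `max_followup` and
#'   `type` describe the fit.
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3), event = c(0, 1, 1))
#' km_curve(d)
#' @export
km_curve <- function(data, arm = NULL, reverse = FALSE) {
  data <- check_survival_data(data, require_arm = !is.null(arm))
  if (!is.null(arm)) {
    data <- data[data$arm == arm, ]
    if (!nrow(data)) abort("no subjects in arm")
  }
  st <- .surv_steps(data$time, data$event, reverse = reverse)
  out <- tibble(time = st$time, n.risk = st$n.risk, n.event = st$n.event,
                estimate = st$estimate)
  structure(out, class = c("rmst_curve", class(out)),
            type = if (reverse) "censoring" else "survival",
            n = st$n, max_followup = st$max_followup, arm = arm)
}

#' Nelson-Aalen cumulative-hazard curve
#'
#' @inheritParams km_curve
#' @return A tibble of class `rmst_curve` (type `"cumhaz"`) with columns
#'   `time`, `n.risk`, `n.event`, `increment` (`dLambda`) and `estimate`
#'   (the cumulative hazard).
#' @export
cumhaz_curve <- function(data, arm = NULL) {
  data <- check_survival_data(data, require_arm = !is.null(arm))
  if (!is.null(arm)) {
    data <- data[data$arm == arm, ]
    if (!nrow(data)) abort("no subjects in arm")
  }
  st <- .surv_steps(data$time, data$event)
  inc <- st$n.event / st$n.risk
  out <- tibble(time = st$time, n.risk = st$n.risk, n.event = st$n.event,
                increment = inc, estimate = cumsum(inc))
  structure(out, class = c("rmst_curve", class(out)), type = "cumhaz",
            n = st$n, max_followup = st$max_followup, arm = arm)
}

#' Counting-process frame with per-subject martingale residual increments
#'
#' Returns the distinct event times within `[0, tau]`, the at-risk fraction
#' normalized by the total sample size, the Nelson-Aalen hazard increments and
#' the per-subject martingale increment matrix
#' `dM[i, k] = dN_i(t_k) - I(X_i >= t_k) dLambda(t_k)`.
#' The increments sum to zero over subjects at every event time.
#'
#' @inheritParams km_curve
#' @param tau Truncation time; event times beyond it are dropped.
#' @param n_total Normalizing total sample size for the at-risk fraction;
#'   defaults to the number of rows used.
#' @return A list with elements `steps` (tibble: `time`, `at_risk`,
#'   `at_risk_frac`, `n.event`, `increment`) and `residuals`
#'   (matrix, subjects x event times).
#' @export
counting_frame <- function(data, arm = NULL, tau = Inf, n_total = NULL) {
  data <- check_survival_data(data, require_arm = !is.null(arm))
  if (!is.null(arm)) {
    data <- data[data$arm == arm, ]
    if (!nrow(data)) abort("no subjects in arm")
  }
  x <- data$time
  d <- data$event
  n_total <- n_total %||% length(x)
  st <- .arm_stats(x, d, n_total, tau)
  K <- length(st$tk)
  dM <- matrix(0, nrow = length(x), ncol = K)
  if (K) {
    for (k in seq_len(K)) {
      dM[, k] <- (x == st$tk[k] & d == 1) - (x >= st$tk[k]) * st$dLam[k]
    }
  }
  list(
    steps = tibble(time = st$tk, at_risk = st$mk,
                   at_risk_frac = st$mk / n_total,
                   n.event = st$dk, increment = st$dLam),
    residuals = dM
  )
}

#' Evaluate a step curve
#'
#' Right-continuous evaluation of an `rmst_curve`; `left = TRUE` gives the
#' left limit (the value just before `t`).
#'
#' @param curve An `rmst_curve`.
#' @param t Vector of times.
#' @param left Evaluate the left limit instead?
#' @return Numeric vector of curve values (origin value 1 for survival-type
#'   curves, 0 for cumulative hazards).
#' @export
curve_value <- function(curve, t, left = FALSE) {
  origin <- if (attr(curve, "type") == "cumhaz") 0 else 1
  if (!nrow(curve)) return(rep(origin, length(t)))
  j <- findInterval(t, curve$time, left.open = left)
  ifelse(j > 0L, curve$estimate[pmax(j, 1L)], origin)
}

#' Integrate the tail of a survival step curve
#'
#' Exact piecewise-constant integral `int_from^to S(u) du` of a
#' (reverse) Kaplan-Meier curve.  When `to` exceeds the largest observed
#' time the curve is extended flat at its last value (with a warning under
#' `extend = "flat"`) or an error is raised (`extend = "error"`).
#'
#' @param curve An `rmst_curve` of type `"survival"` or `"censoring"`.
#' @param from,to Integration limits, `0 <= from <= to`.
#' @param extend Support policy past the largest observed time:
#'   `"flat"` (warn), `"quiet"` or `"error"`.
#' @return The integral, a single number.
#' @examples
#' d <- tibble::tibble(time = 1:3, event = c(1, 1, 1))
#' curve_integral(km_curve(d), 0, 3)
#' @export
curve_integral <- function(curve, from = 0, to,
                           extend = c("flat", "quiet", "error")) {
  extend <- match.arg(extend)
  if (from > to) abort("'from' must not exceed 'to'")
  if (from < 0) abort("'from' must be nonnegative")
  if (attr(curve, "type") == "cumhaz") abort("cannot integrate a cumulative-hazard curve as survival")
  if (extend != "quiet") .check_support(attr(curve, "max_followup"), to, "curve", extend)
  brk <- c(from, curve$time[curve$time > from & curve$time < to], to)
  vals <- curve_value(curve, brk[-length(brk)])
  sum(vals * diff(brk))
}

#' @export
print.rmst_curve <- function(x, ...) {
  cat(sprintf("<rmst_curve: %s, n = %d, %d jump(s), max follow-up %.4g>\n",
              attr(x, "type"), attr(x, "n"), nrow(x), attr(x, "max_followup")))
  NextMethod()
}
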