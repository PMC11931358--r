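# Independent oracles used across the suite.  They are built on
# survival::survfit plus literal loops over the defining sums, so they share
# no code with the package's vectorized implementation.

# integral of a right-continuous step function (origin value 1) over [from, to]
step_area <- function(times, surv, from, to) {
  brk <- c(from, times[times > from & times < to], to)
  val <- vapply(brk[-length(brk)], function(t) {
    i <- which(times <= t)
    if (length(i)) surv[max(i)] else 1
  }, numeric(1))
  sum(val * diff(brk))
}

# one-group summaries from survfit: event times within [0, tau], at-risk and
# event counts, tail areas, RMST and the plug-in variance contribution
# (at-risk fraction normalized by n_tot)
oracle_arm <- function(x, d, n_tot, tau) {
  fit <- survival::survfit(survival::Surv(x, d) ~ 1)
  keep <- fit$n.event > 0 & fit$time <= tau
  tk <- fit$time[keep]
  dk <- fit$n.event[keep]
  mk <- fit$n.risk[keep]
  area <- vapply(tk, function(t) step_area(fit$time, fit$surv, t, tau),
                 numeric(1))
  list(tk = tk, dk = dk, mk = mk, area = area,
       theta = step_area(fit$time, fit$surv, 0, tau),
       sig1 = sum(area^2 / (mk / n_tot) * (dk / mk)))
}

# per-subject martingale-integral scores by nested loops (Eq.-style sums)
oracle_scores <- function(time, event, arm, tau) {
  n <- length(time)
  H <- numeric(n)
  for (z in c(0, 1)) {
    idx <- which(arm == z)
    oa <- oracle_arm(time[idx], event[idx], n, tau)
    sgn <- if (z == 1) -1 else 1
    for (i in idx) {
      gi <- 0
      for (k in seq_along(oa$tk)) {
        w <- oa$area[k] / (oa$mk[k] / n)
        dN <- as.numeric(time[i] == oa$tk[k] && event[i] == 1)
        atr <- as.numeric(time[i] >= oa$tk[k])
        gi <- gi + w * (dN - atr * oa$dk[k] / oa$mk[k])
      }
      H[i] <- sgn * gi
    }
  }
  H
}

# single-group scores with the e-squared weight (reference-data version)
oracle_ref_scores <- function(time, event, tau) {
  n <- length(time)
  oa <- oracle_arm(time, event, n, tau)
  vapply(seq_len(n), function(i) {
    gi <- 0
    for (k in seq_along(oa$tk)) {
      w <- oa$area[k] / (oa$mk[k] / n)
      dN <- as.numeric(time[i] == oa$tk[k] && event[i] == 1)
      atr <- as.numeric(time[i] >= oa$tk[k])
      gi <- gi + w * (dN - atr * oa$dk[k] / oa$mk[k])
    }
    gi
  }, numeric(1))
}

# small random two-arm dataset with ties
random_trial <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    time = round(rexp(n, 0.4), 1) + 0.1,   # rounding forces ties
    event = rbinom(n, 1, 0.7),
    arm = rep_len(c(0, 1), n),
    v1 = rnorm(n), v2 = rnorm(n)
  )
}
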