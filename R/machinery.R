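# Internal counting-process machinery shared by the estimators, the power
# formulas and the simulation engine.
#
# Conventions used throughout (they matter for exact reproducibility):
#  * at-risk fractions are normalized by the *total* sample size, not the arm
#    size, so the variance estimators are variances of sqrt(n) * estimator;
#  * at tied times, events are resolved against the at-risk set that still
#    includes subjects censored at the same time ("events happen first");
#  * survival curves are right-continuous step functions, extended flat past
#    the largest observed time when the truncation time lies beyond it.

# Step representation of a Kaplan-Meier (or reverse Kaplan-Meier) fit:
# jump times, at-risk counts, event counts and the post-jump estimate.
.surv_steps <- function(x, d, reverse = FALSE) {
  n <- length(x)
  xs <- sort(x)
  mf <- if (n) max(x) else 0
  if (!reverse) {
    ev <- x[d == 1]
    if (!length(ev)) {
      return(list(time = numeric(0), n.risk = integer(0), n.event = integer(0),
                  estimate = numeric(0), n = n, max_followup = mf))
    }
    r <- rle(sort(ev))
    tk <- r$values
    dk <- r$lengths
    mk <- n - findInterval(tk, xs, left.open = TRUE)
    est <- cumprod(1 - dk / mk)
  } else {
    cs <- x[d == 0]
    if (!length(cs)) {
      return(list(time = numeric(0), n.risk = integer(0), n.event = integer(0),
                  estimate = numeric(0), n = n, max_followup = mf))
    }
    r <- rle(sort(cs))
    tk <- r$values
    dk <- r$lengths
    atrisk <- n - findInterval(tk, xs, left.open = TRUE)
    # events at exactly tk leave the risk set before the tied censorings
    evs <- sort(x[d == 1])
    tied_events <- findInterval(tk, evs) - findInterval(tk, evs, left.open = TRUE)
    mk <- atrisk - tied_events
    est <- cumprod(1 - dk / mk)
  }
  list(time = tk, n.risk = as.integer(mk), n.event = as.integer(dk),
       estimate = est, n = n, max_followup = mf)
}

# Per-group summaries needed by every estimator: event times within [0, tau],
# Nelson-Aalen increments, tail areas of the KM curve, the RMST, and the
# plug-in variance contribution.  `n_tot` is the normalizing total n.
.arm_stats <- function(x, d, n_tot, tau) {
  st <- .surv_steps(x, d)
  keep <- st$time <= tau
  tk <- st$time[keep]
  dk <- st$n.event[keep]
  mk <- st$n.risk[keep]
  S <- st$estimate[keep]
  K <- length(tk)
  if (K == 0L) {
    return(list(tk = numeric(0), dk = numeric(0), mk = numeric(0),
                S = numeric(0), area = numeric(0), theta = tau, sig1 = 0,
                w = numeric(0), dLam = numeric(0), n_tot = n_tot,
                max_followup = st$max_followup))
  }
  seg <- c(if (K > 1) diff(tk) * S[-K], (tau - tk[K]) * S[K])
  area <- rev(cumsum(rev(seg)))           # area[k] = int_{tk[k]}^{tau} S(u) du
  list(tk = tk, dk = dk, mk = mk, S = S, area = area,
       theta = tk[1] + area[1],
       sig1 = n_tot * sum(area^2 * dk / mk^2),
       w = n_tot * area / mk,             # weight area(t) / Ybar(t)
       dLam = dk / mk,
       n_tot = n_tot, max_followup = st$max_followup)
}

# Per-subject integrals int_0^tau w(t) dMhat_i(t) for the subjects the stats
# in `st` were computed from (one group).  Vectorized over subjects.
.arm_scores <- function(x, d, st, tau) {
  if (!length(st$tk)) return(numeric(length(x)))
  cw <- cumsum(st$w * st$dLam)
  j <- findInterval(pmin(x, tau), st$tk)
  comp <- ifelse(j > 0L, cw[pmax(j, 1L)], 0)
  out <- -comp
  isev <- d == 1 & x <= tau
  out[isev] <- out[isev] + st$w[match(x[isev], st$tk)]
  out
}

.check_support <- function(max_followup, tau, label, extend) {
  if (max_followup < tau) {
    msg <- sprintf(
      "largest observed time (%.4g) in %s is below tau = %.4g; survival curve extended flat",
      max_followup, label, tau)
    if (extend == "error") abort(paste0(msg, " (extend = \"error\")"))
    if (extend == "flat") warn(msg)
  }
  invisible(NULL)
}

# Full two-arm fit: RMSTs, both variance estimators and per-subject scores.
.fit_rmst <- function(time, event, arm, tau, extend = "flat") {
  n <- length(time)
  i1 <- arm == 1
  if (!any(i1)) abort("no subjects in arm 1")
  if (all(i1)) abort("no subjects in arm 0")
  s1 <- .arm_stats(time[i1], event[i1], n, tau)
  s0 <- .arm_stats(time[!i1], event[!i1], n, tau)
  .check_support(s1$max_followup, tau, "arm 1", extend)
  .check_support(s0$max_followup, tau, "arm 0", extend)
  H <- numeric(n)
  # sign convention: minus for the treatment-arm martingale integral
  H[i1] <- -.arm_scores(time[i1], event[i1], s1, tau)
  H[!i1] <- .arm_scores(time[!i1], event[!i1], s0, tau)
  list(n = n, theta1 = s1$theta, theta0 = s0$theta,
       estimate = s1$theta - s0$theta,
       var_plugin = s1$sig1 + s0$sig1,
       var_score = mean(H^2),
       scores = H, s1 = s1, s0 = s0)
}

# Single-group (reference or pooled blinded) design inputs: the local-power
# variance sigma-tilde^2 and, when covariates are supplied, e^2.  Both are
# built from the per-subject martingale-integral scores g_i whose weight
# area(t) / Ybar(t) estimates int_t^tau S0 / {S0(t) G(t)} exactly, by the
# identity S(t-) G(t-) = Ybar(t) under the events-first tie convention.
# sigma-tilde^2 uses the score form {pi(1-pi)}^-1 mean(g_i^2), the
# single-group analogue of the score variance the tests themselves use.
.pooled_inputs <- function(time, event, V, tau, pi = 0.5, extend = "flat",
                           label = "pooled data") {
  n <- length(time)
  st <- .arm_stats(time, event, n, tau)
  .check_support(st$max_followup, tau, label, extend)
  if (!length(st$tk)) {
    warn(sprintf("no events within [0, tau] in %s; sigma_tilde_sq is 0", label))
    return(list(sigma_tilde_sq = 0, e_sq = 0, n = n, stats = st))
  }
  g <- .arm_scores(time, event, st, tau)
  sig <- mean(g^2) / (pi * (1 - pi))
  e2 <- 0
  if (!is.null(V) && ncol(V) > 0L) {
    B <- crossprod(V)
    if (qr(B)$rank < ncol(V)) abort("collinear covariates")
    a <- crossprod(V, g)
    e2 <- drop(crossprod(a, solve(B, a))) / n / (pi * (1 - pi))^2
  }
  list(sigma_tilde_sq = sig, e_sq = e2, n = n, stats = st)
}

# Two-sided local power at standard-normal scale.
.local_power <- function(theta_alt, v, alpha) {
  pnorm(qnorm(alpha / 2) - theta_alt / v) +
    1 - pnorm(qnorm(1 - alpha / 2) - theta_alt / v)
}
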