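test_that("exponential rates from survival probabilities", {
  expect_equal(exp_rate_from_survival(exp(-1), 1), 1)
  expect_equal(exp_rate_from_survival(0.520, 1825), 3.58e-4, tolerance = 2e-3)
  expect_equal(exp_rate_from_survival(0.965, 1825), 1.95e-5, tolerance = 2e-3)
  expect_error(exp_rate_from_survival(1.2, 10), "in \\(0, 1\\)")
})

test_that("parametric tail integrals use the closed forms", {
  lam <- log(5) / 5
  s0 <- dist_exponential(lam)
  expect_equal(rmstaug:::.spec_tail(s0, 0, 5), (1 - exp(-5 * lam)) / lam)
  expect_equal(rmstaug:::.spec_tail(s0, 0, 5), 4 / log(5), tolerance = 1e-10)
  expect_equal(rmstaug:::.spec_tail(s0, 5, 5), 0)
  # piecewise-exponential tail checked against quadrature
  pw <- dist_piecewise_exponential(c(0.3, 0.15), cutpoints = 1)
  qd <- integrate(function(t) exp(-rmstaug:::.pwexp_cumhaz(pw, t)), 0.4, 5,
                  rel.tol = 1e-10)$value
  expect_equal(rmstaug:::.spec_tail(pw, 0.4, 5), qd, tolerance = 1e-8)
})

test_that("sigma_tilde_sq vanishes without event mass and matches the MC oracle", {
  no_ev <- km_curve(tibble::tibble(time = c(6, 7, 8), event = c(0, 0, 0)))
  expect_warning(out <- sigma_tilde_sq(dist_km(no_ev), dist_uniform(8), 5),
                 "no event mass")
  expect_equal(out, 0)

  # null trials: Var(sqrt(n) theta_hat) should match sigma_tilde within 10%
  sc_sigma <- sigma_tilde_sq(dist_exponential(log(5) / 5), dist_uniform(8), 5)
  reps <- 800; n <- 500
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- sim_trial("1b", n = n, seed = 40000 + r)
    est[r] <- sum(rmst(d, 5)$rmst * c(-1, 1))
  }
  expect_lt(abs(n * var(est) - sc_sigma) / sc_sigma, 0.10)
})

test_that("step-curve and parametric sigma_tilde_sq agree on the same law", {
  d <- sim_reference("2b", 4000, seed = 55)
  est <- sigma_tilde_sq(dist_km(km_curve(d[c("time", "event")])),
                        dist_km(km_curve(d[c("time", "event")], reverse = TRUE)),
                        tau = 5)
  par <- sigma_tilde_sq(dist_exponential(log(5) / 5), dist_uniform(8), 5)
  expect_lt(abs(est - par) / par, 0.15)
})

test_that("local power is alpha at the null center and monotone", {
  s2 <- 14.7
  p0 <- predicted_power(0, 500, s2, e_sq = 4, alpha = 0.05)
  expect_equal(p0$power_standard, 0.05, tolerance = 1e-12)
  expect_equal(p0$power_augmented, 0.05, tolerance = 1e-12)
  grid_n <- predicted_power(0.5, seq(100, 900, 100), s2)
  expect_true(all(diff(grid_n$power_standard) > 0))
  th <- vapply(seq(0.1, 1, 0.1),
               function(t) predicted_power(t, 400, s2)$power_standard,
               numeric(1))
  expect_true(all(diff(th) > 0))
  expect_error(predicted_power(0.5, 500, 10, e_sq = 41), "exceeds total")
  expect_error(predicted_power(0.5, 500, 10, e_sq = 1, pi = 0.3),
               "equal allocation")
})

test_that("predicted power is invariant to a common time-unit rescaling", {
  lamS <- exp_rate_from_survival(0.52, 1825)
  lamG <- exp_rate_from_survival(0.965, 1825)
  p_days <- predicted_power(150, 490,
                            sigma_tilde_sq(dist_exponential(lamS),
                                           dist_exponential(lamG), 1825))
  p_years <- predicted_power(150 / 365.25, 490,
                             sigma_tilde_sq(dist_exponential(lamS * 365.25),
                                            dist_exponential(lamG * 365.25),
                                            1825 / 365.25))
  expect_equal(p_days$power_standard, p_years$power_standard, tolerance = 1e-7)
})

test_that("e_squared obeys its exact identities and the scalar oracle", {
  ref <- sim_reference("2a", 150, seed = 61)
  ref$const <- 1
  expect_equal(e_squared(ref, 5, covariates = "const"), 0, tolerance = 1e-20)

  # single covariate: scalar formula on oracle scores, including the
  # {pi(1-pi)}^-2 normalization that puts e^2 on the Q2 = pi(1-pi) e^2 scale
  g <- oracle_ref_scores(ref$time, ref$event, tau = 5)
  scalar <- 16 * sum(g * ref$v1)^2 / (nrow(ref) * sum(ref$v1^2))
  expect_equal(e_squared(ref, 5, covariates = "v1"), scalar, tolerance = 1e-10)

  # adding a covariate never decreases e^2
  e1 <- e_squared(ref, 5, covariates = "v1")
  e12 <- e_squared(ref, 5, covariates = c("v1", "v2"))
  expect_gte(e12, e1 - 1e-12)

  ref$v3 <- -3 * ref$v2
  expect_error(e_squared(ref, 5, covariates = c("v2", "v3")), "collinear")
  d <- sim_trial("2a", 100, seed = 62)
  expect_error(e_squared(d, 5, covariates = "v1"), "control-only")
})

test_that("required_n agrees with an exhaustive grid scan", {
  s2 <- sigma_tilde_sq(dist_exponential(log(5) / 5), dist_uniform(8), 5)
  th <- true_rmst_diff("2a")
  req <- required_n(th, s2, target_power = 0.8, n_min = 100, n_max = 2000)
  # independent scan
  grid <- seq(100, 2000, 10)
  pw <- vapply(grid, function(n) {
    v <- sqrt(s2 / n)
    pnorm(qnorm(0.025) - th / v) + 1 - pnorm(qnorm(0.975) - th / v)
  }, numeric(1))
  expect_equal(req$n, grid[which(pw >= 0.8)[1]])
  expect_gte(req$power, 0.8)
  expect_lt(pw[match(req$n, grid) - 1], 0.8)
  # doubling the alternative shrinks the requirement
  req2 <- required_n(2 * th, s2, target_power = 0.8, n_min = 100, n_max = 2000)
  expect_lt(req2$n, req$n)
  expect_error(required_n(0.01, s2, target_power = 0.8, n_max = 200),
               "not reached")
})
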