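test_that("Kaplan-Meier handles the no-event and no-censoring extremes", {
  all_cens <- tibble::tibble(time = c(1, 2, 3), event = c(0, 0, 0))
  crv <- km_curve(all_cens)
  expect_equal(nrow(crv), 0)
  expect_equal(curve_value(crv, c(0, 1.5, 3)), c(1, 1, 1))
  expect_equal(cumhaz_curve(all_cens)$estimate, numeric(0))

  all_ev <- tibble::tibble(time = c(1, 2, 3), event = c(1, 1, 1))
  crv <- km_curve(all_ev)
  expect_equal(crv$time, c(1, 2, 3))
  expect_equal(crv$estimate, c(2/3, 1/3, 0))
})

test_that("product-limit estimate matches the hand-computed oracle with censoring", {
  d <- tibble::tibble(time = c(1, 2, 3), event = c(0, 1, 1))
  crv <- km_curve(d)
  expect_equal(curve_value(crv, c(0.5, 1.5, 2, 2.9, 3.5)),
               c(1, 1, 1/2, 1/2, 0))
})

test_that("Kaplan-Meier agrees with survival::survfit on tied data", {
  d <- random_trial(60, seed = 101)
  for (a in c(0, 1)) {
    sub <- d[d$arm == a, ]
    fit <- survival::survfit(survival::Surv(sub$time, sub$event) ~ 1)
    crv <- km_curve(d, arm = a)
    keep <- fit$n.event > 0
    expect_equal(crv$time, fit$time[keep])
    expect_equal(crv$estimate, fit$surv[keep], tolerance = 1e-12)
    expect_equal(crv$n.risk, fit$n.risk[keep])
  }
})

test_that("Nelson-Aalen increments cumulate as direct summation says", {
  d <- tibble::tibble(time = c(1, 2, 3), event = c(1, 1, 1))
  ch <- cumhaz_curve(d)
  expect_equal(ch$increment, c(1/3, 1/2, 1))
  expect_equal(ch$estimate[3], 11/6)
})

test_that("reverse Kaplan-Meier resolves ties with events first", {
  # censoring at t = 1 competes with an event at t = 1: the event leaves the
  # risk set first, so G jumps by 1 - 1/2
  d <- tibble::tibble(time = c(1, 1, 2), event = c(1, 0, 0))
  g <- km_curve(d, reverse = TRUE)
  expect_equal(g$time, c(1, 2))
  expect_equal(g$estimate, c(1/2, 0))
})

test_that("the product of KM and reverse KM equals the empirical at-risk fraction", {
  d <- random_trial(80, seed = 7)
  s <- km_curve(d[c("time", "event")])
  g <- km_curve(d[c("time", "event")], reverse = TRUE)
  for (t in sort(unique(d$time))) {
    expect_equal(curve_value(s, t, left = TRUE) * curve_value(g, t, left = TRUE),
                 mean(d$time >= t), tolerance = 1e-12)
  }
})

test_that("tail integration is exact, additive, and guards its limits", {
  d <- tibble::tibble(time = c(1, 2, 3), event = c(0, 0, 0))
  crv <- km_curve(d)
  expect_equal(suppressWarnings(curve_integral(crv, 0, 5)), 5)  # S identically 1
  expect_equal(curve_integral(crv, 3, 3, extend = "quiet"), 0)
  expect_error(curve_integral(crv, 2, 1), "must not exceed")
  expect_error(curve_integral(crv, 0, 5, extend = "error"), "extended flat|extend")
  expect_warning(curve_integral(crv, 0, 5), "extended flat")

  d2 <- random_trial(40, seed = 12)
  crv2 <- km_curve(d2[c("time", "event")])
  mf <- attr(crv2, "max_followup")
  a <- 0.3; b <- 1.7; cc <- min(3.9, mf)
  expect_equal(curve_integral(crv2, a, cc, extend = "quiet"),
               curve_integral(crv2, a, b, extend = "quiet") +
                 curve_integral(crv2, b, cc, extend = "quiet"),
               tolerance = 1e-12)
  # against the independent step-sum oracle
  fit <- survival::survfit(survival::Surv(d2$time, d2$event) ~ 1)
  expect_equal(curve_integral(crv2, 0, cc, extend = "quiet"),
               step_area(fit$time, fit$surv, 0, cc), tolerance = 1e-12)
})

test_that("martingale residual increments sum to zero at every event time", {
  d <- random_trial(50, seed = 33)
  for (a in c(0, 1)) {
    cf <- counting_frame(d, arm = a, tau = 4)
    if (ncol(cf$residuals)) {
      expect_equal(colSums(cf$residuals), rep(0, nrow(cf$steps)),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
    expect_true(all(diff(cf$steps$at_risk) <= 0))
  }
})

test_that("empty arms are rejected", {
  d <- tibble::tibble(time = c(1, 2), event = c(1, 1), arm = c(0, 0))
  expect_error(km_curve(d, arm = 1), "no subjects")
})
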