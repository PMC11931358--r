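test_that("a zero coefficient reproduces the standard test exactly", {
  d <- sim_trial("2a", n = 200, seed = 21)
  base <- rmst_test(d, tau = 5)
  aug0 <- rmst_augmented_test(d, tau = 5, covariates = c("v1", "v2"),
                              coefficient = 0)
  expect_equal(aug0$estimate, base$estimate)
  expect_equal(aug0$var_aug, base$var_score)
  expect_equal(aug0$p.value, base$p.value)
})

test_that("the coefficient is the least-squares slope of the scores", {
  d <- sim_trial("2a", n = 300, seed = 22)
  fit <- rmst_augmented_test(d, tau = 5, covariates = c("v1", "v2"))
  # with pi = 1/2, (Z - pi)^2 = 1/4 identically, so c_hat solves the
  # ordinary normal equations of H on (Z - pi) V
  X <- cbind((d$arm - 0.5) * d$v1, (d$arm - 0.5) * d$v2)
  ls <- stats::lm.fit(X, fit$scores)$coefficients
  expect_equal(unname(fit$c_hat), unname(ls), tolerance = 1e-10)
})

test_that("rescaling covariates halves the coefficient but not the estimate", {
  d <- sim_trial("2a", n = 200, seed = 23)
  f1 <- rmst_augmented_test(d, tau = 5, covariates = c("v1", "v2"))
  d2 <- dplyr::mutate(d, v1 = 2 * v1, v2 = 2 * v2)
  f2 <- rmst_augmented_test(d2, tau = 5, covariates = c("v1", "v2"))
  expect_equal(f2$c_hat, f1$c_hat / 2, tolerance = 1e-12)
  expect_equal(f2$estimate, f1$estimate, tolerance = 1e-12)
  expect_equal(f2$var_aug, f1$var_aug, tolerance = 1e-12)
})

test_that("the estimate is invariant under invertible covariate transforms", {
  d <- sim_trial("3a", n = 250, seed = 24)
  f1 <- rmst_augmented_test(d, tau = 5, covariates = c("v1", "v2"))
  A <- matrix(c(2, -1, 0.5, 3), 2)
  VW <- as.matrix(d[c("v1", "v2")]) %*% A
  d2 <- dplyr::mutate(d, v1 = VW[, 1], v2 = VW[, 2])
  f2 <- rmst_augmented_test(d2, tau = 5, covariates = c("v1", "v2"))
  expect_equal(f2$estimate, f1$estimate, tolerance = 1e-10)
  expect_equal(f2$var_aug, f1$var_aug, tolerance = 1e-10)
  # conditioning-only standardization changes nothing either
  f3 <- rmst_augmented_test(d, tau = 5, covariates = c("v1", "v2"),
                            standardize = TRUE)
  expect_equal(f3$estimate, f1$estimate, tolerance = 1e-10)
})

test_that("augmentation never inflates the score variance at equal allocation", {
  for (s in 1:15) {
    d <- random_trial(40, seed = 300 + s)
    f <- tryCatch(rmst_augmented_test(d, tau = 3, covariates = c("v1", "v2"),
                                      extend = "quiet"),
                  error = function(e) NULL)
    if (is.null(f)) next
    expect_lte(f$var_aug, f$var_score + 1e-12)
  }
})

test_that("projection onto independent noise covariates is null", {
  set.seed(25)
  d <- sim_trial("1b", n = 5000)
  d$noise1 <- rnorm(5000)
  d$noise2 <- rnorm(5000)
  f <- rmst_augmented_test(d, tau = 5, covariates = c("noise1", "noise2"))
  H <- f$scores
  for (v in c("noise1", "noise2")) {
    # moment-based standard error of the projection slope
    se <- 4 * sd((d$arm - 0.5) * d[[v]] * H) / sqrt(5000) / mean(d[[v]]^2)
    expect_lt(abs(f$c_hat[[v]]), 3 * se)
  }
})

test_that("collinear covariates are a hard error unless explicitly allowed", {
  d <- sim_trial("2a", n = 100, seed = 26)
  d$v3 <- 2 * d$v1
  expect_error(rmst_augmented_test(d, tau = 5, covariates = c("v1", "v3")),
               "collinear")
  f <- rmst_augmented_test(d, tau = 5, covariates = c("v1", "v3"),
                           allow_singular = TRUE)
  f1 <- rmst_augmented_test(d, tau = 5, covariates = "v1")
  expect_equal(f$estimate, f1$estimate, tolerance = 1e-8)
})

test_that("the augmented estimator is unbiased for the true difference", {
  reps <- 400
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- sim_trial("2a", n = 500, seed = 5000 + r)
    est[r] <- rmst_augmented_test(d, tau = 5, covariates = c("v1", "v2"))$estimate
  }
  bias <- mean(est) - true_rmst_diff("2a")
  expect_lt(abs(bias), 3 * sd(est) / sqrt(reps))
})
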