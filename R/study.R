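# Replication harness for the operating-characteristics study: empirical
# size/power of both tests, design-stage predicted power over reference sets,
# and the full blinded sample-size re-estimation loop.

# Per-replicate seeds derived from one master seed by a counter scheme, so
# replicates are order-independent and each study function is reproducible
# from a single integer.  Kept below 2^31 - 1.
.rep_seed <- function(master, counter, stream = 0L) {
  (abs(master) + 1000003 * counter + 7777771 * stream) %% 2147483647
}

# fast path: both tests on raw vectors, no data-frame overhead
.fast_tests <- function(time, event, arm, V, tau, alpha, pi) {
  fit <- .fit_rmst(time, event, arm, tau, extend = "quiet")
  z_std <- fit$estimate / sqrt(fit$var_score / fit$n)
  out <- c(p_standard = 2 * pnorm(-abs(z_std)), p_augmented = NA_real_)
  if (!is.null(V)) {
    ch <- .chat(fit$scores, arm, V, pi)
    adj <- (arm - pi) * drop(V %*% ch)
    est <- fit$estimate - mean(adj)
    va <- mean((fit$scores - adj)^2)
    out["p_augmented"] <- 2 * pnorm(-abs(est / sqrt(va / fit$n)))
  }
  out
}

#' Empirical size and power of the RMST tests
#'
#' Simulates `reps` trials per scenario and reports the rejection fraction of
#' the standard and augmented tests at level `alpha`.
#'
#' @param scenarios Character vector of scenario ids (see [sim_scenario()]).
#' @param n Subjects per trial.
#' @param reps Number of replicates.
#' @param tau Truncation time.
#' @param alpha Two-sided significance level.
#' @param covariates Covariates for the augmented test (columns of the
#'   simulated data).
#' @param tests Which tests to report.
#' @param seed Master seed; replicate seeds are derived by a counter scheme.
#' @return A tibble: `scenario`, `test`, `n`, `reps`, `reject`
#'   (the empirical rejection rate) and its binomial `mc_se`.
#' @examples
#' study_operating_characteristics("2a", n = 200, reps = 50, seed = 1)
#' @export
study_operating_characteristics <- function(scenarios, n = 500, reps = 1000,
                                            tau = 5, alpha = 0.05,
                                            covariates = c("v1", "v2"),
                                            tests = c("standard", "augmented"),
                                            seed = 1) {
  tests <- match.arg(tests, several.ok = TRUE)
  purrr::map_dfr(scenarios, function(id) {
    sc <- sim_scenario(id)
    want_aug <- "augmented" %in% tests
    ps <- matrix(NA_real_, nrow = reps, ncol = 2)
    for (r in seq_len(reps)) {
      set.seed(.rep_seed(seed, r))
      v <- .sim_vectors(sc, n)
      V <- if (want_aug) cbind(v1 = v$v1, v2 = v$v2)[, covariates, drop = FALSE] else NULL
      ps[r, ] <- .fast_tests(v$time, v$event, v$arm, V, tau, alpha, sc$pi)
    }
    purrr::map_dfr(tests, function(tst) {
      p <- ps[, if (tst == "standard") 1 else 2]
      rej <- mean(p < alpha)
      tibble(scenario = sc$id, test = tst, n = n, reps = reps,
             reject = rej, mc_se = sqrt(rej * (1 - rej) / reps))
    })
  })
}

#' Design-stage predicted power over simulated reference sets
#'
#' Draws `reps` control-only reference datasets (matched or covariate
#' mis-matched), computes the blinded design inputs from each, and averages
#' the predicted power of both tests at sample size `n`.
#'
#' @inheritParams study_operating_characteristics
#' @param n_ref Reference subjects per set.
#' @param matched Matched (`TRUE`) or covariate-truncated mis-matched
#'   (`FALSE`) reference sampling.
#' @param theta_alt Alternative for the power formula; `NULL` uses the
#'   scenario's true RMST difference.
#' @param pi Allocation probability.
#' @return A tibble: `scenario`, `matched`, `test`, `n`, `n_ref`, `reps`,
#'   mean predicted power `mean_pp`, its across-set `sd` and Monte-Carlo
#'   standard error `mc_se`.
#' @export
study_predicted_power <- function(scenarios, reps = 1000, n_ref = 200,
                                  n = 500, tau = 5, alpha = 0.05,
                                  covariates = c("v1", "v2"),
                                  matched = TRUE, theta_alt = NULL,
                                  pi = 0.5, seed = 1) {
  purrr::map_dfr(scenarios, function(id) {
    sc <- sim_scenario(id)
    th <- theta_alt %||% true_rmst_diff(sc)
    pp <- matrix(NA_real_, nrow = reps, ncol = 2)
    for (r in seq_len(reps)) {
      set.seed(.rep_seed(seed, r, stream = 1L))
      ref <- if (matched) {
        .sim_control_vectors(sc, n_ref)
      } else {
        acc <- NULL
        while (is.null(acc) || length(acc$time) < n_ref) {
          cand <- .sim_control_vectors(sc, 4L * n_ref)
          keep <- cand$v1 < 1 & cand$v2 < 1
          kept <- lapply(cand, `[`, keep)
          acc <- if (is.null(acc)) kept else Map(c, acc, kept)
        }
        lapply(acc, head, n_ref)
      }
      V <- cbind(v1 = ref$v1, v2 = ref$v2)[, covariates, drop = FALSE]
      inp <- .pooled_inputs(ref$time, ref$event, V, tau, pi = pi,
                            extend = "quiet")
      q2 <- pi * (1 - pi) * inp$e_sq
      pp[r, 1] <- .local_power(th, sqrt(inp$sigma_tilde_sq / n), alpha)
      if (q2 < inp$sigma_tilde_sq) {
        pp[r, 2] <- .local_power(th, sqrt((inp$sigma_tilde_sq - q2) / n), alpha)
      }
    }
    purrr::map_dfr(c("standard", "augmented"), function(tst) {
      x <- pp[, if (tst == "standard") 1 else 2]
      tibble(scenario = sc$id, matched = matched, test = tst, n = n,
             n_ref = n_ref, reps = reps, theta_alt = th,
             mean_pp = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE),
             mc_se = sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))
    })
  })
}

#' Operating characteristics of the blinded re-estimation loop
#'
#' Replicates the full design: simulate a trial stream, take a blinded
#' snapshot of the first `n_mid` subjects followed to `tau`, re-estimate the
#' required sample size from the pooled snapshot, then run the final test on
#' the first `n_final` subjects of the same stream.  Reports the rejection
#' rate and the distribution of the selected sample sizes.
#'
#' @inheritParams study_operating_characteristics
#' @param n_mid Subjects in the blinded snapshot.
#' @param target_power Target power driving the re-estimation.
#' @param step Sample-size grid step.
#' @param theta_alt Target RMST difference for the power formula; `NULL`
#'   uses the design target shared by the alternative scenarios (the true
#'   difference of scenario 2, about 0.514) for every scenario, including
#'   the null ones.
#' @param n_cap Largest sample size the stream supports (grid upper bound).
#' @return A tibble per scenario and test: rejection rate `reject` with
#'   `mc_se`, and the `min`, `q1`, `median`, `q3`, `max` of the selected
#'   sample sizes (quantiles taken on the grid).
#' @export
study_ssr <- function(scenarios, reps = 1000, n_mid = 200,
                      target_power = 0.8, step = 10, tau = 5, alpha = 0.05,
                      covariates = c("v1", "v2"),
                      tests = c("standard", "augmented"), theta_alt = NULL,
                      n_cap = 1500, seed = 1) {
  tests <- match.arg(tests, several.ok = TRUE)
  th <- theta_alt %||% true_rmst_diff("2a")
  pi <- 0.5
  purrr::map_dfr(scenarios, function(id) {
    sc <- sim_scenario(id)
    grid <- seq(n_mid, n_cap, by = step)
    sel <- matrix(NA_real_, nrow = reps, ncol = 2)
    rej <- matrix(NA, nrow = reps, ncol = 2)
    for (r in seq_len(reps)) {
      set.seed(.rep_seed(seed, r, stream = 2L))
      v <- .sim_vectors(sc, n_cap)
      idx <- seq_len(n_mid)
      Vm <- cbind(v1 = v$v1, v2 = v$v2)[, covariates, drop = FALSE]
      inp <- .pooled_inputs(v$time[idx], v$event[idx],
                            if ("augmented" %in% tests) Vm[idx, , drop = FALSE] else NULL,
                            tau, pi = pi, extend = "quiet")
      for (tst in tests) {
        j <- if (tst == "standard") 1L else 2L
        q2 <- if (tst == "augmented") pi * (1 - pi) * inp$e_sq else 0
        if (q2 >= inp$sigma_tilde_sq) next
        pw <- .local_power(th, sqrt((inp$sigma_tilde_sq - q2) / grid), alpha)
        hit <- which(pw >= target_power)
        if (!length(hit)) next
        nf <- max(grid[hit[1]], n_mid)
        sel[r, j] <- nf
        ii <- seq_len(nf)
        p <- .fast_tests(v$time[ii], v$event[ii], v$arm[ii],
                         if (tst == "augmented") Vm[ii, , drop = FALSE] else NULL,
                         tau, alpha, pi)
        rej[r, j] <- p[[if (tst == "standard") "p_standard" else "p_augmented"]] < alpha
      }
    }
    purrr::map_dfr(tests, function(tst) {
      j <- if (tst == "standard") 1L else 2L
      ok <- !is.na(sel[, j])
      q <- quantile(sel[ok, j], c(0, 0.25, 0.5, 0.75, 1), type = 1)
      rr <- mean(rej[ok, j])
      tibble(scenario = sc$id, test = tst, reps = sum(ok), n_mid = n_mid,
             target_power = target_power, theta_alt = th,
             reject = rr, mc_se = sqrt(rr * (1 - rr) / sum(ok)),
             n_min = q[[1]], n_q1 = q[[2]], n_median = q[[3]],
             n_q3 = q[[4]], n_max = q[[5]])
    })
  })
}

#' Run a full simulation study from a configuration
#'
#' Orchestrates [study_operating_characteristics()],
#' [study_predicted_power()] and [study_ssr()] from one configuration list
#' (or YAML file): keys `scenarios`, `n`, `reps`, `tau`, `alpha`,
#' `covariates`, `tests`, `seed`, plus optional sub-lists `reference`
#' (`reps`, `n_ref`, `matched`, `theta_alt`) and `ssr` (`reps`, `n_mid`,
#' `target_power`, `step`, `n_cap`, `theta_alt`).
#'
#' @param config A named list or the path of a YAML file.
#' @return A list with elements `operating`, and, when configured,
#'   `predicted` and `ssr`, each a summary tibble.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- .read_config(config)
  known <- c("scenarios", "n", "reps", "tau", "alpha", "covariates", "tests",
             "seed", "reference", "ssr")
  bad <- setdiff(names(config), known)
  if (length(bad)) abort(sprintf("invalid config keys: %s", paste(bad, collapse = ", ")))
  base <- list(scenarios = config$scenarios %||% .scenario_ids,
               n = config$n %||% 500, reps = config$reps %||% 1000,
               tau = config$tau %||% 5, alpha = config$alpha %||% 0.05,
               covariates = config$covariates %||% c("v1", "v2"),
               tests = config$tests %||% c("standard", "augmented"),
               seed = config$seed %||% 1)
  out <- list(operating = do.call(study_operating_characteristics, base))
  if (!is.null(config$reference)) {
    rf <- config$reference
    out$predicted <- bind_rows(lapply(
      if (is.null(rf$matched)) c(TRUE, FALSE) else as.logical(rf$matched),
      function(m) study_predicted_power(
        base$scenarios, reps = rf$reps %||% base$reps,
        n_ref = rf$n_ref %||% 200, n = base$n, tau = base$tau,
        alpha = base$alpha, covariates = base$covariates, matched = m,
        theta_alt = rf$theta_alt, seed = base$seed)))
  }
  if (!is.null(config$ssr)) {
    sr <- config$ssr
    out$ssr <- study_ssr(base$scenarios, reps = sr$reps %||% base$reps,
                         n_mid = sr$n_mid %||% 200,
                         target_power = sr$target_power %||% 0.8,
                         step = sr$step %||% 10, tau = base$tau,
                         alpha = base$alpha, covariates = base$covariates,
                         tests = base$tests, theta_alt = sr$theta_alt,
                         n_cap = sr$n_cap %||% 1500, seed = base$seed)
  }
  out
}
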