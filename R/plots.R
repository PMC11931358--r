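#' Plot a step curve
#'
#' @param object An `rmst_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmst_curve <- function(object, ...) {
  type <- attr(object, "type")
  origin <- if (type == "cumhaz") 0 else 1
  df <- tibble(time = c(0, object$time),
               estimate = c(origin, object$estimate))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "time",
      y = switch(type, survival = "survival probability",
                 censoring = "censoring survival G(t)",
                 cumhaz = "cumulative hazard")) +
    ggplot2::theme_minimal()
}

#' Plot the Kaplan-Meier curves behind an RMST test
#'
#' Draws both arms' survival curves and shades the area between them up to
#' the truncation time, the quantity the test compares.
#'
#' @param object An `rmst_test` (or `rmst_aug_test`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmst_test <- function(object, ...) {
  crv <- object$curves
  df <- bind_rows(
    tibble(time = 0, estimate = 1, arm = c(0, 1)),
    crv[c("time", "estimate", "arm")]
  )
  df$arm <- factor(df$arm, levels = c(1, 0), labels = c("treatment", "control"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$estimate,
                                   colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$tau, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability", colour = NULL,
                  subtitle = sprintf("RMST difference %.3g (p = %.3g) at tau = %g",
                                     object$estimate, object$p.value, object$tau)) +
    ggplot2::theme_minimal()
}

#' Plot a power-versus-sample-size scan
#'
#' @param object An `rmst_samplesize` or `rmst_reestimate` object.
#' @param ... Unused.
#' @return A ggplot of both tests' predicted power against `n`, with the
#'   target power and the selected `n` marked.
#' @export
autoplot.rmst_samplesize <- function(object, ...) {
  tab <- tidyr::pivot_longer(object$table,
                             c("power_standard", "power_augmented"),
                             names_to = "test", names_prefix = "power_",
                             values_to = "power")
  ggplot2::ggplot(tab, ggplot2::aes(.data$n, .data$power,
                                    colour = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$target_power, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = if (!is.null(object$n_final)) object$n_final else object$n,
                        linetype = "dotted") +
    ggplot2::labs(x = "total sample size n", y = "predicted power",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rmst_samplesize
#' @export
autoplot.rmst_reestimate <- autoplot.rmst_samplesize

#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL
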