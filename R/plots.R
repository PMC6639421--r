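#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an observed-versus-predicted NTT diagnostic
#'
#' Scatter of per-subject predicted mean NTT against observed NTT with the
#' identity line; tight scatter around the identity indicates the model
#' reproduces individual non-adherence patterns.
#'
#' @param object An `ntt_diagnostic` from [ntt_diagnostic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ntt_diagnostic
#' @export
autoplot.ntt_diagnostic <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$observed_ntt, y = .data$predicted_mean_ntt)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(
      x = "Observed NTT (days)", y = "Predicted mean NTT (days)",
      title = sprintf("Observed vs predicted non-therapeutic time (%s)", object$model),
      subtitle = sprintf("Pearson correlation %.3f over %d subjects",
                         object$correlation, nrow(object$summary))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulated concentration profile
#'
#' @param object A `concentration_profile` from [simulate_profile()].
#' @param threshold Horizontal reference line (ng/mL; default 40). `NA` omits
#'   it.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concentration_profile
#' @export
autoplot.concentration_profile <- function(object, threshold = 40, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time / 24, y = .data$conc)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (days)", y = "Concentration (ng/mL)") +
    ggplot2::theme_minimal()
  if (!is.na(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "red3")
  }
  p
}

#' Plot a covariate's comparative adherence-exposure panel
#'
#' Concentration curves per covariate category with dose markers near the
#' time axis: filled points are doses taken, open points doses missed.
#'
#' @param object A `covariate_profile_panel` from [covariate_profile_panel()].
#' @param threshold Protection threshold line (ng/mL, default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot covariate_profile_panel
#' @export
autoplot.covariate_profile_panel <- function(object, threshold = 40, ...) {
  ggplot2::ggplot(object$profiles, ggplot2::aes(x = .data$time / 24, y = .data$conc)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "red3") +
    ggplot2::geom_point(
      data = object$doses,
      ggplot2::aes(x = .data$time / 24, y = -10, shape = .data$taken),
      size = 1.5, show.legend = FALSE
    ) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::facet_wrap(~category, ncol = 1) +
    ggplot2::labs(x = "Time (days)", y = "Concentration (ng/mL)",
                  title = paste("Adherence-driven exposure by", object$covariate)) +
    ggplot2::theme_minimal()
}

#' Plot fitted odds ratios with confidence intervals
#'
#' Forest-style display of [odds_ratios()] output, one panel per transition
#' logit, with the unity reference line.
#'
#' @param fit A `markov_fit`.
#' @param conf.level Confidence level (default 0.95).
#' @return A ggplot object.
#' @export
plot_odds_ratios <- function(fit, conf.level = 0.95) {
  ors <- odds_ratios(fit, conf.level = conf.level)
  ggplot2::ggplot(ors, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~parameter, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
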