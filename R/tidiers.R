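#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted Markov adherence model
#'
#' @param x A `markov_fit` object.
#' @param exponentiate If `TRUE`, report odds-ratio scale estimates and
#'   intervals (`exp(beta)`).
#' @param conf.int Include Wald confidence bounds (default `TRUE`).
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect parameter: `term`,
#'   `parameter` (`p01`/`p10`), `estimate`, `std.error`, `statistic`,
#'   `p.value`, and `conf.low`/`conf.high` when requested.
#' @method tidy markov_fit
#' @export
tidy.markov_fit <- function(x, exponentiate = FALSE, conf.int = TRUE,
                            conf.level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  out <- x$coefficients |>
    dplyr::mutate(
      std.error = .data$se,
      statistic = .data$estimate / .data$se,
      p.value = 2 * stats::pnorm(-abs(.data$statistic))
    )
  if (conf.int) {
    out <- out |>
      dplyr::mutate(conf.low = .data$estimate - z * .data$se,
                    conf.high = .data$estimate + z * .data$se)
  }
  if (exponentiate) {
    for (cl in intersect(c("estimate", "conf.low", "conf.high"), names(out))) {
      out[[cl]] <- exp(out[[cl]])
    }
  }
  dplyr::select(out, -"se")
}

#' @rdname tidy.markov_fit
#' @method tidy bernoulli_fit
#' @export
tidy.bernoulli_fit <- tidy.markov_fit

#' One-row summary of a fitted Markov adherence model
#'
#' @param x A `markov_fit` or `bernoulli_fit` object.
#' @param ... Unused.
#' @return A tibble with the objective-function value (`neg2ll`, i.e. minus
#'   twice the marginal log-likelihood), log-likelihood, counts, estimation
#'   method and convergence flag.
#' @method glance markov_fit
#' @export
glance.markov_fit <- function(x, ...) {
  tibble::tibble(
    neg2ll = x$neg2ll,
    logLik = x$logLik,
    n_subjects = x$n_subjects,
    n_transitions = x$n_transitions,
    n_effects = sum(x$coefficients$term != "(Intercept)"),
    method = x$method,
    random = if (!is.null(x$random)) x$random else "intercept",
    converged = x$converged
  )
}

#' @rdname glance.markov_fit
#' @method glance bernoulli_fit
#' @export
glance.bernoulli_fit <- glance.markov_fit
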