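#' Build the full covariate model specification
#'
#' Assigns every retained covariate to both the `P01` and `P10` logits,
#' forming the full model from which backward elimination starts. Covariates
#' flagged by the transition-sparsity screen ([screen_covariates()]) are
#' excluded up front.
#'
#' @param covariates Character vector: the covariate registry (indicator
#'   column names; a multi-level covariate contributes one indicator per
#'   non-reference level).
#' @param screen Optional tibble from [screen_covariates()]; covariates with
#'   `keep = FALSE` are removed. Screening is typically run on the underlying
#'   categorical column, so `screen_map` can translate a screened name to the
#'   indicator columns it governs.
#' @param screen_map Optional named list: screened covariate name ->
#'   character vector of indicator columns to drop with it.
#' @return A list with elements `p01` and `p10` (character vectors), class
#'   `model_spec`.
#' @export
full_model_spec <- function(covariates, screen = NULL, screen_map = NULL) {
  assert_that(length(covariates) > 0, "covariate registry is empty")
  dropped <- character()
  if (!is.null(screen)) {
    for (cv in screen$covariate[!screen$keep]) {
      dropped <- c(dropped, screen_map[[cv]] %||% cv)
    }
  }
  keep <- setdiff(covariates, dropped)
  structure(list(p01 = keep, p10 = keep, screened_out = intersect(covariates, dropped)),
            class = "model_spec")
}

#' Backward elimination on odds-ratio confidence intervals
#'
#' Iteratively fits the model and removes non-significant covariate effects:
#' at each iteration every effect whose 95% Wald confidence interval for the
#' odds ratio includes unity is dropped (all at once by default, or only the
#' weakest one with `drop = "one"`), and the reduced model is refitted until
#' no effect drops. Effects are eliminated per covariate-parameter pair, so a
#' covariate may remain on one logit only.
#'
#' @param transitions Tibble from [build_transitions()].
#' @param spec A `model_spec` from [full_model_spec()], or a list with
#'   character elements `p01` and `p10`.
#' @param drop `"all"` (default) removes every failing effect per iteration;
#'   `"one"` removes only the effect whose CI centre is closest to unity.
#' @param conf.level Confidence level of the Wald interval (default 0.95).
#' @inheritParams fit_markov
#' @return A list of class `selection_result`: `fit` (final `markov_fit`),
#'   `history` (tibble with one row per effect per iteration: estimate, CI,
#'   dropped flag), `iterations`, `converged`.
#' @export
backward_eliminate <- function(transitions, spec, drop = c("all", "one"),
                               conf.level = 0.95,
                               random = c("separate", "shared", "none"),
                               method = c("laplace", "agq"), nodes = 32,
                               control = list()) {
  drop <- match.arg(drop)
  random <- match.arg(random)
  method <- match.arg(method)
  p01 <- spec$p01; p10 <- spec$p10
  history <- list()
  fit <- NULL
  max_iter <- length(p01) + length(p10) + 1
  for (iter in seq_len(max_iter)) {
    fit <- fit_markov(transitions, p01 = p01, p10 = p10, random = random,
                      method = method, nodes = nodes, control = control)
    ors <- odds_ratios(fit, conf.level = conf.level)
    if (!fit$converged) {
      history[[iter]] <- dplyr::mutate(ors, iteration = iter, dropped = FALSE,
                                       note = "non-convergence; elimination halted")
      warning("fit did not converge at iteration ", iter,
              "; elimination halted with partial result", call. = FALSE)
      break
    }
    failing <- ors$ci_low <= 1 & ors$ci_high >= 1
    if (drop == "one" && sum(failing) > 1) {
      dist <- abs(log(ors$or))
      keep_one <- which(failing)[which.min(dist[failing])]
      failing <- seq_len(nrow(ors)) == keep_one
    }
    history[[iter]] <- dplyr::mutate(ors, iteration = iter, dropped = failing,
                                     note = NA_character_)
    if (!any(failing)) break
    for (i in which(failing)) {
      if (ors$parameter[i] == "p01") p01 <- setdiff(p01, ors$term[i])
      else p10 <- setdiff(p10, ors$term[i])
    }
  }
  history <- dplyr::bind_rows(history) |>
    dplyr::relocate("iteration")
  structure(list(fit = fit, history = history,
                 iterations = max(history$iteration),
                 final_p01 = p01, final_p10 = p10,
                 converged = fit$converged),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Backward elimination on OR confidence intervals\n")
  cat(sprintf("  %d iteration(s); final model: %d effect(s) on P01, %d on P10\n",
              x$iterations, length(x$final_p01), length(x$final_p10)))
  dropped <- x$history[x$history$dropped, ]
  if (nrow(dropped) > 0) {
    for (i in seq_len(nrow(dropped))) {
      cat(sprintf("  iter %d: dropped %s on %s (OR %.3f, CI %.3f-%.3f)\n",
                  dropped$iteration[i], dropped$term[i], dropped$parameter[i],
                  dropped$or[i], dropped$ci_low[i], dropped$ci_high[i]))
    }
  }
  invisible(x)
}
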