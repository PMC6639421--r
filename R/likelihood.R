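#' Model parameters for the two-state Markov chain
#'
#' Bundles the logit-scale intercepts, covariate coefficients and
#' random-effect variances of the two-state first-order Markov model of daily
#' adherence. `P01` (dose-missing to dose-taking, re-initiation) and `P10`
#' (dose-taking to dose-missing, discontinuation) each have a logit that is
#' intercept + covariates x coefficients + subject random effect; `P00` and
#' `P11` are their complements.
#'
#' @param theta1 Logit intercept of `P01`.
#' @param theta2 Logit intercept of `P10`.
#' @param beta01,beta10 Named numeric vectors of covariate coefficients
#'   (log odds ratios) on the `P01` and `P10` logits.
#' @param omega_sq Random-effect variance(s): for `random = "separate"` a
#'   length-2 vector (variance of the `P01` and `P10` effects, recycled if
#'   length 1); for `"shared"` a single variance of one effect added to both
#'   logits; for `"none"` ignored.
#' @param random Random-effect structure: `"separate"` (default), `"shared"`,
#'   or `"none"`.
#' @return An object of class `markov_params`.
#' @export
markov_params <- function(theta1, theta2, beta01 = c(), beta10 = c(),
                          omega_sq = c(0, 0),
                          random = c("separate", "shared", "none")) {
  random <- match.arg(random)
  beta01 <- unlist(beta01); beta10 <- unlist(beta10)
  if (length(beta01) > 0) assert_that(!is.null(names(beta01)) && all(nzchar(names(beta01))),
                                      "beta01 must be a named vector")
  if (length(beta10) > 0) assert_that(!is.null(names(beta10)) && all(nzchar(names(beta10))),
                                      "beta10 must be a named vector")
  if (random == "separate" && length(omega_sq) == 1) omega_sq <- rep(omega_sq, 2)
  assert_that(all(omega_sq >= 0), "omega_sq must be non-negative")
  structure(list(theta1 = theta1, theta2 = theta2,
                 beta01 = beta01, beta10 = beta10,
                 omega_sq = omega_sq, random = random),
            class = "markov_params")
}

#' @export
print.markov_params <- function(x, ...) {
  cat("Two-state Markov model parameters\n")
  cat(sprintf("  theta1 (P01 logit): %.4f   theta2 (P10 logit): %.4f\n", x$theta1, x$theta2))
  if (length(x$beta01)) cat("  beta01:", paste0(names(x$beta01), "=", signif(x$beta01, 4), collapse = ", "), "\n")
  if (length(x$beta10)) cat("  beta10:", paste0(names(x$beta10), "=", signif(x$beta10, 4), collapse = ", "), "\n")
  cat(sprintf("  random effects: %s, omega_sq = %s\n", x$random,
              paste(signif(x$omega_sq, 4), collapse = ", ")))
  invisible(x)
}

#' Transition probabilities at given covariates and random effects
#'
#' Evaluates the four transition probabilities. The `P01` logit is
#' `theta1 + x'beta01 + eta1`, the `P10` logit is `theta2 + x'beta10 + eta2`;
#' `P00 = 1 - P01` and `P11 = 1 - P10`.
#'
#' @param params A [markov_params()] object.
#' @param covariates Named numeric vector (or 1-row data frame) of covariate
#'   values; must contain every name used in `beta01`/`beta10`. May be empty.
#' @param eta Numeric vector `c(eta1, eta2)` of random-effect values on the
#'   `P01` and `P10` logits (a single value is used for both; default 0).
#' @return A named numeric vector `p01`, `p10`, `p00`, `p11`.
#' @examples
#' p <- markov_params(theta1 = 0, theta2 = log(2))
#' transition_probabilities(p) # p01 = 0.5, p10 = 2/3
#' @export
transition_probabilities <- function(params, covariates = NULL, eta = c(0, 0)) {
  if (length(eta) == 1) eta <- rep(eta, 2)
  x <- covariate_vector(covariates, union(names(params$beta01), names(params$beta10)))
  l1 <- params$theta1 + lincomb(x, params$beta01) + eta[1]
  l2 <- params$theta2 + lincomb(x, params$beta10) + eta[2]
  p01 <- expit(l1); p10 <- expit(l2)
  c(p01 = p01, p10 = p10, p00 = 1 - p01, p11 = 1 - p10)
}

covariate_vector <- function(covariates, needed) {
  if (length(needed) == 0) return(numeric())
  assert_that(!is.null(covariates), paste0("covariate values required for: ",
                                           paste(needed, collapse = ", ")))
  if (is.data.frame(covariates)) covariates <- unlist(covariates[1, , drop = TRUE])
  missing_cov <- setdiff(needed, names(covariates))
  assert_that(length(missing_cov) == 0,
              paste0("unregistered covariate(s): ", paste(missing_cov, collapse = ", ")))
  covariates
}

lincomb <- function(x, beta) {
  if (length(beta) == 0) return(0)
  sum(x[names(beta)] * beta)
}

#' Conditional negative log-likelihood of one subject's transitions
#'
#' Minus the log-likelihood of a subject's observed day-to-day transitions
#' given fixed random-effect values: the sum over days of minus the log of the
#' transition probability matching (previous state, current state), computed
#' on the log scale throughout.
#'
#' @param subject_data Tibble with columns `prev_state`, `state` and any
#'   covariate columns used by `params` (one row per day, in order).
#' @param params A [markov_params()] object.
#' @param eta Random-effect values `c(eta1, eta2)`.
#' @return A single number (negative log conditional likelihood).
#' @export
conditional_nll <- function(subject_data, params, eta = c(0, 0)) {
  if (length(eta) == 1) eta <- rep(eta, 2)
  l1 <- params$theta1 + design_lp(subject_data, params$beta01) + eta[1]
  l2 <- params$theta2 + design_lp(subject_data, params$beta10) + eta[2]
  from0 <- subject_data$prev_state == 0
  y01 <- subject_data$state[from0]          # 1 = re-initiated
  y10 <- 1 - subject_data$state[!from0]     # 1 = discontinued
  -(sum(y01 * l1[from0] - log1pexp(l1[from0])) +
      sum(y10 * l2[!from0] - log1pexp(l2[!from0])))
}

design_lp <- function(df, beta) {
  if (length(beta) == 0) return(rep(0, nrow(df)))
  missing_cov <- setdiff(names(beta), names(df))
  assert_that(length(missing_cov) == 0,
              paste0("unregistered covariate(s): ", paste(missing_cov, collapse = ", ")))
  as.matrix(df[names(beta)]) %*% beta
}

# ---- internal likelihood engine -------------------------------------------
#
# With separate random effects the Markov likelihood factorizes into two
# conditionally independent random-intercept logistic likelihoods: days with
# prev_state 0 inform the P01 logit (response: current state), days with
# prev_state 1 inform the P10 logit (response: 1 - current state). Each
# subject's rows collapse exactly to cells of (trials n, successes k) per
# unique covariate row, because the likelihood depends on the data only
# through those sufficient statistics.

make_cells <- function(transitions, logit = c("p01", "p10"), covariates = character(),
                       subjects = NULL) {
  logit <- match.arg(logit)
  keep <- if (logit == "p01") transitions$prev_state == 0 else transitions$prev_state == 1
  df <- transitions[keep, , drop = FALSE]
  y <- if (logit == "p01") df$state else 1L - df$state
  subjects <- subjects %||% sort(unique(transitions$subject_id))
  if (nrow(df) == 0) {
    return(list(subj = integer(), n = numeric(), k = numeric(),
                X = matrix(0, 0, length(covariates), dimnames = list(NULL, covariates)),
                m = length(subjects), subjects = subjects))
  }
  key <- df[, c("subject_id", covariates), drop = FALSE]
  key$.y <- y
  agg <- key |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject_id", covariates)))) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$.y), .groups = "drop")
  list(subj = match(agg$subject_id, subjects),
       n = as.numeric(agg$n), k = as.numeric(agg$k),
       X = as.matrix(agg[, covariates, drop = FALSE]),
       m = length(subjects), subjects = subjects)
}

rowsum_by <- function(x, idx, m) {
  out <- numeric(m)
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

# Posterior modes of the subject random effects for one logistic likelihood
# with offsets a (per cell) and N(0, omega_sq) prior: damped vectorized Newton.
inner_modes <- function(a, cells, omega_sq, eta = NULL) {
  m <- cells$m
  eta <- eta %||% numeric(m)
  if (length(cells$subj) == 0) {
    return(list(eta = numeric(m), h = rep(1 / omega_sq, m), lc = numeric(m)))
  }
  for (it in seq_len(200)) {
    lp <- a + eta[cells$subj]
    p <- expit(lp)
    g <- rowsum_by(cells$k - cells$n * p, cells$subj, m) - eta / omega_sq
    h <- rowsum_by(cells$n * p * (1 - p), cells$subj, m) + 1 / omega_sq
    step <- pmin(pmax(g / h, -4), 4)
    step[!is.finite(step)] <- 0
    eta <- eta + step
    if (max(abs(step)) < 1e-10) break
  }
  lp <- a + eta[cells$subj]
  p <- expit(lp)
  lc <- rowsum_by(cells$k * lp - cells$n * log1pexp(lp), cells$subj, m)
  h <- rowsum_by(cells$n * p * (1 - p), cells$subj, m) + 1 / omega_sq
  list(eta = eta, h = h, lc = lc)
}

# Marginal log-likelihood of one logistic random-intercept block.
# method "laplace": mode + curvature; "agq": adaptive Gauss-Hermite with
# `nodes` points centred at the mode. omega_sq = 0 degenerates to eta = 0.
glmm_block_ll <- function(a, cells, omega_sq, method = "laplace", nodes = 32,
                          eta_start = NULL) {
  m <- cells$m
  if (omega_sq <= 0) {
    if (length(cells$subj) == 0) return(list(ll = 0, ll_i = numeric(m), eta = numeric(m), h = rep(Inf, m)))
    lc <- rowsum_by(cells$k * a - cells$n * log1pexp(a), cells$subj, m)
    return(list(ll = sum(lc), ll_i = lc, eta = numeric(m), h = rep(Inf, m)))
  }
  md <- inner_modes(a, cells, omega_sq, eta_start)
  if (method == "laplace") {
    ll_i <- md$lc - md$eta^2 / (2 * omega_sq) - 0.5 * log(omega_sq * md$h)
  } else {
    gh <- pracma::gaussHermite(nodes)
    sd_q <- sqrt(2 / md$h)
    fq <- matrix(0, m, nodes)
    for (q in seq_len(nodes)) {
      eta_q <- md$eta + sd_q * gh$x[q]
      lp <- a + eta_q[cells$subj]
      lc_q <- rowsum_by(cells$k * lp - cells$n * log1pexp(lp), cells$subj, m)
      fq[, q] <- lc_q - eta_q^2 / (2 * omega_sq) - 0.5 * log(2 * pi * omega_sq) +
        log(gh$w[q]) + gh$x[q]^2
    }
    fmax <- apply(fq, 1, max)
    ll_i <- fmax + log(rowSums(exp(fq - fmax))) + log(sd_q)
  }
  list(ll = sum(ll_i), ll_i = ll_i, eta = md$eta, h = md$h)
}

# Shared random effect: one eta per subject enters both logits. Cells of both
# blocks are concatenated; offsets must be supplied per concatenated cell.
glmm_shared_ll <- function(a1, cells1, a2, cells2, omega_sq, method = "laplace",
                           nodes = 32, eta_start = NULL) {
  cells <- list(subj = c(cells1$subj, cells2$subj),
                n = c(cells1$n, cells2$n), k = c(cells1$k, cells2$k),
                m = cells1$m, subjects = cells1$subjects)
  glmm_block_ll(c(a1, a2), cells, omega_sq, method, nodes, eta_start)
}

#' Marginal objective function of a fitted or hypothesised model
#'
#' Minus twice the marginal log-likelihood of the transition data under a
#' [markov_params()] object, integrating the subject random effects out of the
#' conditional Markov likelihood by Laplace approximation or adaptive
#' Gauss-Hermite quadrature. This is the objective-function value used to
#' compare model fits.
#'
#' @param transitions Tibble from [build_transitions()] with any covariate
#'   columns referenced by `params`.
#' @param params A [markov_params()] object.
#' @param method `"laplace"` (default) or `"agq"`.
#' @param nodes Number of quadrature nodes when `method = "agq"`.
#' @return Minus twice the marginal log-likelihood (a single number).
#' @export
marginal_nll <- function(transitions, params, method = c("laplace", "agq"), nodes = 32) {
  method <- match.arg(method)
  subjects <- sort(unique(transitions$subject_id))
  c1 <- make_cells(transitions, "p01", names(params$beta01), subjects)
  c2 <- make_cells(transitions, "p10", names(params$beta10), subjects)
  a1 <- block_offsets(params$theta1, params$beta01, c1)
  a2 <- block_offsets(params$theta2, params$beta10, c2)
  ll <- switch(params$random,
    none = glmm_block_ll(a1, c1, 0)$ll + glmm_block_ll(a2, c2, 0)$ll,
    separate = glmm_block_ll(a1, c1, params$omega_sq[1], method, nodes)$ll +
      glmm_block_ll(a2, c2, params$omega_sq[2], method, nodes)$ll,
    shared = glmm_shared_ll(a1, c1, a2, c2, params$omega_sq[1], method, nodes)$ll
  )
  -2 * ll
}
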