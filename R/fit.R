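#' Fit the two-state Markov mixed-effects adherence model
#'
#' Maximum-likelihood fit of the discrete-time two-state Markov model: the
#' `P01` (re-initiation) and `P10` (discontinuation) logits each carry an
#' intercept, optional covariate effects, and a subject-level normal random
#' effect whose integral is approximated by the Laplace method (default) or
#' adaptive Gauss-Hermite quadrature. Standard errors come from a central
#' finite-difference Hessian of the negative marginal log-likelihood at the
#' optimum; empirical-Bayes (posterior-mode) random effects are stored per
#' subject.
#'
#' @param transitions Tibble from [build_transitions()], including every
#'   covariate column named in `p01`/`p10`.
#' @param p01,p10 Character vectors of covariate column names entering the
#'   `P01` and `P10` logits (log odds-ratio coding; indicator columns against
#'   a reference level).
#' @param random Random-effect structure: `"separate"` (one effect per logit,
#'   default), `"shared"` (one effect on both logits), or `"none"`.
#' @param method Integral approximation, `"laplace"` (default) or `"agq"`.
#' @param nodes Quadrature nodes for `"agq"`.
#' @param start Optional [markov_params()] used as starting values; defaults
#'   to empirical logits of the pooled transition frequencies, zero
#'   coefficients, and omega-squared 0.1.
#' @param control Passed to [stats::optim()] (BFGS).
#' @return An object of class `markov_fit`: see [tidy.markov_fit()],
#'   [glance.markov_fit()], [odds_ratios()], [empirical_bayes_matrices()].
#' @examples
#' s <- tibble::tibble(subject_id = rep(c("A", "B"), each = 6),
#'                     day = rep(1:6, 2),
#'                     state = c(1L,1L,0L,0L,1L,1L, 1L,0L,1L,1L,1L,0L))
#' tr <- build_transitions(s)
#' fit <- fit_markov(tr, random = "none")
#' glance(fit)
#' @export
fit_markov <- function(transitions, p01 = character(), p10 = character(),
                       random = c("separate", "shared", "none"),
                       method = c("laplace", "agq"), nodes = 32,
                       start = NULL, control = list()) {
  random <- match.arg(random)
  method <- match.arg(method)
  check_covariate_columns(transitions, union(p01, p10))
  subjects <- sort(unique(transitions$subject_id))
  c1 <- make_cells(transitions, "p01", p01, subjects)
  c2 <- make_cells(transitions, "p10", p10, subjects)
  start <- start %||% default_start(c1, c2, p01, p10, random)
  control <- utils::modifyList(list(maxit = 1000, reltol = 1e-12), control)

  if (random %in% c("separate", "none")) {
    om1 <- if (random == "none") NULL else start$omega_sq[1]
    om2 <- if (random == "none") NULL else start$omega_sq[2]
    b1 <- fit_block(c1, start$theta1, start$beta01, om1, method, nodes, control)
    b2 <- fit_block(c2, start$theta2, start$beta10, om2, method, nodes, control)
    ll <- b1$ll + b2$ll
    converged <- b1$converged && b2$converged
    params <- markov_params(b1$theta, b2$theta, b1$beta, b2$beta,
                            omega_sq = c(b1$omega_sq %||% 0, b2$omega_sq %||% 0),
                            random = random)
    coefs <- dplyr::bind_rows(block_coefs(b1, "p01"), block_coefs(b2, "p10"))
    vcov <- block_diag(b1$vcov, b2$vcov)
    rownames(vcov) <- colnames(vcov) <- c(paste0("p01:", c("(Intercept)", names(b1$beta))),
                                          paste0("p10:", c("(Intercept)", names(b2$beta))))
    ebe <- tibble::tibble(subject_id = subjects, eta_p01 = b1$eta, eta_p10 = b2$eta)
    omega_tbl <- tibble::tibble(parameter = c("p01", "p10"),
                                omega_sq = c(b1$omega_sq %||% 0, b2$omega_sq %||% 0))
    diagnostics <- list(p01 = b1$optim, p10 = b2$optim)
  } else {
    sh <- fit_shared(c1, c2, start, method, nodes, control)
    ll <- sh$ll
    converged <- sh$converged
    params <- sh$params
    coefs <- sh$coefs
    vcov <- sh$vcov
    ebe <- tibble::tibble(subject_id = subjects, eta_p01 = sh$eta, eta_p10 = sh$eta)
    omega_tbl <- tibble::tibble(parameter = "shared", omega_sq = params$omega_sq[1])
    diagnostics <- list(joint = sh$optim)
  }

  structure(list(
    coefficients = coefs,
    params = params,
    omega = omega_tbl,
    vcov = vcov,
    neg2ll = -2 * ll,
    logLik = ll,
    converged = converged,
    diagnostics = diagnostics,
    ebe = ebe,
    subject_covariates = modal_covariates(transitions, union(p01, p10)),
    p01_covariates = p01, p10_covariates = p10,
    random = random, method = method, nodes = nodes,
    n_subjects = length(subjects),
    n_transitions = nrow(transitions),
    counts = count_transitions(transitions)
  ), class = "markov_fit")
}

check_covariate_columns <- function(transitions, covs) {
  missing_cols <- setdiff(covs, names(transitions))
  assert_that(length(missing_cols) == 0,
              paste0("covariate column(s) absent from transitions: ",
                     paste(missing_cols, collapse = ", ")))
  for (cv in covs) {
    assert_that(is.numeric(transitions[[cv]]) && !anyNA(transitions[[cv]]),
                paste0("covariate '", cv, "' must be numeric without NAs ",
                       "(code categories as 0/1 indicators)"))
  }
}

default_start <- function(c1, c2, p01, p10, random) {
  emp_logit <- function(cells) {
    n <- sum(cells$n); k <- sum(cells$k)
    logit(clip_prob((k + 0.5) / (n + 1), 1e-6))
  }
  markov_params(emp_logit(c1), emp_logit(c2),
                stats::setNames(rep(0, length(p01)), p01),
                stats::setNames(rep(0, length(p10)), p10),
                omega_sq = if (random == "none") c(0, 0) else c(0.1, 0.1),
                random = if (random == "none") "none" else random)
}

# One random-intercept logistic block: optimize (theta, beta, log omega_sq).
fit_block <- function(cells, theta0, beta0, omega_sq0, method, nodes, control) {
  nbeta <- length(beta0)
  has_om <- !is.null(omega_sq0)
  eta_env <- new.env(parent = emptyenv()); eta_env$eta <- NULL
  nll <- function(par) {
    if (any(!is.finite(par))) return(1e12)
    a <- block_offsets(par[1], if (nbeta) par[2:(1 + nbeta)] else NULL, cells)
    om <- if (has_om) exp(pmin(pmax(par[length(par)], -30), 30)) else 0
    res <- glmm_block_ll(a, cells, om, method, nodes, eta_env$eta)
    if (!is.finite(res$ll)) return(1e12)
    eta_env$eta <- res$eta
    -res$ll
  }
  par0 <- c(theta0, unname(beta0), if (has_om) log(omega_sq0))
  opt <- stats::optim(par0, nll, method = "BFGS", control = control)
  H <- fd_hessian(nll, opt$par)
  vc <- safe_solve(H)
  nfix <- 1 + nbeta
  theta <- opt$par[1]
  beta <- stats::setNames(if (nbeta) opt$par[2:(1 + nbeta)] else numeric(), names(beta0))
  omega_sq <- if (has_om) exp(opt$par[length(opt$par)]) else NULL
  a <- block_offsets(theta, beta, cells)
  final <- glmm_block_ll(a, cells, omega_sq %||% 0, method, nodes, eta_env$eta)
  list(theta = theta, beta = beta, omega_sq = omega_sq,
       se = sqrt(pmax(diag(vc)[seq_len(nfix)], 0)),
       vcov = vc[seq_len(nfix), seq_len(nfix), drop = FALSE],
       ll = final$ll, eta = final$eta,
       converged = opt$convergence == 0 && all(is.finite(diag(vc)[seq_len(nfix)])),
       optim = opt[c("convergence", "counts", "value")])
}

# Per-cell linear-predictor offsets of one logit block (always cell-length).
block_offsets <- function(theta, beta, cells) {
  if (length(cells$subj) == 0) return(numeric(0))
  a <- theta + if (length(beta)) drop(cells$X %*% beta) else 0
  rep_len(a, length(cells$n))
}

block_coefs <- function(b, parameter) {
  tibble::tibble(
    term = c("(Intercept)", names(b$beta)),
    parameter = parameter,
    estimate = c(b$theta, unname(b$beta)),
    se = b$se
  )
}

fit_shared <- function(c1, c2, start, method, nodes, control) {
  n1 <- length(start$beta01); n2 <- length(start$beta10)
  eta_env <- new.env(parent = emptyenv()); eta_env$eta <- NULL
  unpack <- function(par) {
    list(theta1 = par[1],
         beta01 = stats::setNames(par[seq_len(n1) + 1], names(start$beta01)),
         theta2 = par[n1 + 2],
         beta10 = stats::setNames(par[seq_len(n2) + n1 + 2], names(start$beta10)),
         omega_sq = exp(par[n1 + n2 + 3]))
  }
  nll <- function(par) {
    if (any(!is.finite(par))) return(1e12)
    p <- unpack(par)
    p$omega_sq <- min(max(p$omega_sq, 1e-13), 1e13)
    a1 <- block_offsets(p$theta1, p$beta01, c1)
    a2 <- block_offsets(p$theta2, p$beta10, c2)
    res <- glmm_shared_ll(a1, c1, a2, c2, p$omega_sq, method, nodes, eta_env$eta)
    if (!is.finite(res$ll)) return(1e12)
    eta_env$eta <- res$eta
    -res$ll
  }
  par0 <- c(start$theta1, unname(start$beta01), start$theta2, unname(start$beta10),
            log(start$omega_sq[1]))
  opt <- stats::optim(par0, nll, method = "BFGS", control = control)
  H <- fd_hessian(nll, opt$par)
  vc <- safe_solve(H)
  p <- unpack(opt$par)
  nfix <- n1 + n2 + 2
  se <- sqrt(pmax(diag(vc)[seq_len(nfix)], 0))
  params <- markov_params(p$theta1, p$theta2, p$beta01, p$beta10,
                          omega_sq = p$omega_sq, random = "shared")
  a1 <- block_offsets(p$theta1, p$beta01, c1)
  a2 <- block_offsets(p$theta2, p$beta10, c2)
  final <- glmm_shared_ll(a1, c1, a2, c2, p$omega_sq, method, nodes, eta_env$eta)
  coefs <- tibble::tibble(
    term = c("(Intercept)", names(p$beta01), "(Intercept)", names(p$beta10)),
    parameter = rep(c("p01", "p10"), c(n1 + 1, n2 + 1)),
    estimate = c(p$theta1, unname(p$beta01), p$theta2, unname(p$beta10)),
    se = se
  )
  vcf <- vc[seq_len(nfix), seq_len(nfix), drop = FALSE]
  rownames(vcf) <- colnames(vcf) <- paste0(coefs$parameter, ":", coefs$term)
  list(ll = final$ll, converged = opt$convergence == 0 && all(is.finite(se)),
       params = params, coefs = coefs, vcov = vcf, eta = final$eta,
       optim = opt[c("convergence", "counts", "value")])
}

# Central finite-difference Hessian, step 1e-4 on the working scale.
fd_hessian <- function(f, par, step = 1e-4) {
  p <- length(par)
  H <- matrix(0, p, p)
  f0 <- f(par)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p); ei[i] <- step; ej[j] <- step
      if (i == j) {
        H[i, i] <- (f(par + ei) - 2 * f0 + f(par - ei)) / step^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(par + ei + ej) - f(par + ei - ej) - f(par - ei + ej) + f(par - ei - ej)) /
          (4 * step^2)
      }
    }
  }
  H
}

safe_solve <- function(H) {
  out <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(out) || any(diag(out) < 0)) {
    warning("Hessian not positive definite at the optimum; standard errors unreliable",
            call. = FALSE)
    if (is.null(out)) out <- matrix(NA_real_, nrow(H), ncol(H))
  }
  out
}

block_diag <- function(A, B) {
  out <- matrix(0, nrow(A) + nrow(B), ncol(A) + ncol(B))
  out[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  out[nrow(A) + seq_len(nrow(B)), ncol(A) + seq_len(ncol(B))] <- B
  out
}

modal_covariates <- function(transitions, covs) {
  if (length(covs) == 0) {
    return(tibble::tibble(subject_id = sort(unique(transitions$subject_id))))
  }
  transitions |>
    dplyr::count(dplyr::across(dplyr::all_of(c("subject_id", covs)))) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    dplyr::arrange(.data$subject_id)
}

#' Fit the Bernoulli (coin-flip) comparator model
#'
#' The logistic comparator treats each day's dose-taking as an independent
#' Bernoulli draw with a single subject-specific probability: one logit with
#' intercept and subject random effect, ignoring the previous day's state.
#' Used as the baseline against which the Markov model's objective-function
#' drop and predictive checks are judged.
#'
#' @inheritParams fit_markov
#' @param covariates Optional covariate columns on the single logit.
#' @param random `"intercept"` (subject random effect, default) or `"none"`.
#' @return An object of class `bernoulli_fit`.
#' @export
fit_bernoulli <- function(transitions, covariates = character(),
                          random = c("intercept", "none"),
                          method = c("laplace", "agq"), nodes = 32,
                          control = list()) {
  random <- match.arg(random)
  method <- match.arg(method)
  check_covariate_columns(transitions, covariates)
  subjects <- sort(unique(transitions$subject_id))
  # all days inform the single dose-taking probability P1
  df <- transitions
  df$prev_state <- 0L   # reuse the p01 cell builder: response = state
  cells <- make_cells(df, "p01", covariates, subjects)
  control <- utils::modifyList(list(maxit = 1000, reltol = 1e-12), control)
  p1_emp <- clip_prob((sum(cells$k) + 0.5) / (sum(cells$n) + 1), 1e-6)
  b <- fit_block(cells, logit(p1_emp),
                 stats::setNames(rep(0, length(covariates)), covariates),
                 if (random == "none") NULL else 0.1, method, nodes, control)
  structure(list(
    coefficients = block_coefs(b, "p1"),
    theta1 = b$theta, beta = b$beta, omega_sq = b$omega_sq %||% 0,
    vcov = b$vcov,
    neg2ll = -2 * b$ll, logLik = b$ll,
    converged = b$converged, diagnostics = b$optim,
    ebe = tibble::tibble(subject_id = subjects, eta = b$eta),
    subject_covariates = modal_covariates(transitions, covariates),
    covariates = covariates, random = random, method = method, nodes = nodes,
    n_subjects = length(subjects), n_transitions = nrow(transitions)
  ), class = "bernoulli_fit")
}

#' Wald odds ratios of the fitted covariate effects
#'
#' One row per covariate-parameter assignment: the odds ratio `exp(beta)` and
#' its 95% Wald confidence interval `exp(beta +/- 1.96 se)`. Effects whose
#' standard error is unavailable are returned without an interval and flagged.
#'
#' @param fit A `markov_fit` (or `bernoulli_fit`) object.
#' @param conf.level Confidence level (default 0.95; the multiplier is the
#'   corresponding normal quantile, 1.96 at 0.95).
#' @return A tibble `term`, `parameter`, `or`, `ci_low`, `ci_high`,
#'   `se_missing`.
#' @export
odds_ratios <- function(fit, conf.level = 0.95) {
  # conventional fixed multiplier at the default level
  z <- if (conf.level == 0.95) 1.96 else stats::qnorm(1 - (1 - conf.level) / 2)
  fit$coefficients |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(
      or = exp(.data$estimate),
      ci_low = exp(.data$estimate - z * .data$se),
      ci_high = exp(.data$estimate + z * .data$se),
      se_missing = !is.finite(.data$se)
    ) |>
    dplyr::select("term", "parameter", "or", "ci_low", "ci_high", "se_missing")
}

#' Individual empirical-Bayes transition matrices
#'
#' Evaluates each subject's transition probabilities at their posterior-mode
#' random effects and their covariate values (by default, the subject's modal
#' covariate vector over follow-up; supply `newdata` to override). Rows of
#' each 2x2 matrix sum to one by construction.
#'
#' @param fit A `markov_fit` or `bernoulli_fit` object.
#' @param newdata Optional tibble `subject_id` + covariate columns replacing
#'   the stored modal covariates.
#' @return A tibble `subject_id`, `p01`, `p10`, `p00`, `p11`. For a Bernoulli
#'   fit the next state is independent of the current one, so `p01 = p11` and
#'   `p10 = p00`.
#' @export
empirical_bayes_matrices <- function(fit, newdata = NULL) {
  UseMethod("empirical_bayes_matrices")
}

#' @export
empirical_bayes_matrices.markov_fit <- function(fit, newdata = NULL) {
  cov_tbl <- newdata %||% fit$subject_covariates
  missing_subj <- setdiff(fit$ebe$subject_id, cov_tbl$subject_id)
  assert_that(length(missing_subj) == 0,
              paste0("no covariate row for subject(s): ",
                     paste(utils::head(missing_subj, 5), collapse = ", ")))
  df <- dplyr::left_join(fit$ebe, cov_tbl, by = "subject_id")
  l1 <- fit$params$theta1 + design_lp(df, fit$params$beta01) + df$eta_p01
  l2 <- fit$params$theta2 + design_lp(df, fit$params$beta10) + df$eta_p10
  tibble::tibble(subject_id = df$subject_id,
                 p01 = expit(l1), p10 = expit(l2),
                 p00 = 1 - expit(l1), p11 = 1 - expit(l2))
}

#' @export
empirical_bayes_matrices.bernoulli_fit <- function(fit, newdata = NULL) {
  cov_tbl <- newdata %||% fit$subject_covariates
  df <- dplyr::left_join(fit$ebe, cov_tbl, by = "subject_id")
  p1 <- expit(fit$theta1 + design_lp(df, fit$beta) + df$eta)
  tibble::tibble(subject_id = df$subject_id,
                 p01 = p1, p10 = 1 - p1, p00 = 1 - p1, p11 = p1)
}

#' Compare the Markov and Bernoulli objective functions
#'
#' @param markov A `markov_fit`.
#' @param bernoulli A `bernoulli_fit` on the same transition data.
#' @return A tibble with each model's minus twice log-likelihood and the drop
#'   (Bernoulli minus Markov; positive favours the Markov model).
#' @export
compare_models <- function(markov, bernoulli) {
  assert_that(markov$n_transitions == bernoulli$n_transitions,
              "models were fitted to different numbers of transitions")
  tibble::tibble(
    model = c("bernoulli", "markov"),
    neg2ll = c(bernoulli$neg2ll, markov$neg2ll),
    drop_vs_bernoulli = c(0, bernoulli$neg2ll - markov$neg2ll)
  )
}

#' @export
print.markov_fit <- function(x, ...) {
  cat("Two-state Markov mixed-effects adherence model\n")
  cat(sprintf("  %d subjects, %d transitions; %s%s, random effects: %s\n",
              x$n_subjects, x$n_transitions, x$method,
              if (x$method == "agq") paste0("(", x$nodes, ")") else "", x$random))
  cat(sprintf("  -2 log-likelihood: %.2f   converged: %s\n", x$neg2ll, x$converged))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @export
print.bernoulli_fit <- function(x, ...) {
  cat("Bernoulli (coin-flip) adherence model\n")
  cat(sprintf("  %d subjects, %d days; -2 log-likelihood: %.2f   converged: %s\n",
              x$n_subjects, x$n_transitions, x$neg2ll, x$converged))
  cat(sprintf("  P1 (typical) = %.4f, omega_sq = %.4f\n", expit(x$theta1), x$omega_sq))
  invisible(x)
}
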