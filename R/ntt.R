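#' Observed non-therapeutic time of a daily state series
#'
#' Non-therapeutic time (NTT) is the cumulative number of unprotected days
#' caused by consecutive missed doses, assuming each dose protects for 24 h:
#' within a run of `k >= 2` consecutive zeros, the first missed day is still
#' covered by the previous dose, so the run contributes `k - 1` days (two
#' sequential missed doses count as one NTT day, and each further consecutive
#' miss adds one). Isolated missed days contribute nothing. The alternative
#' accounting in which a run of `k >= 2` zeros contributes all `k` days is
#' available as `rule = "run"`.
#'
#' @param states Integer/numeric vector of daily 0/1 states (or a per-day
#'   tibble with a `state` column for a single subject).
#' @param rule `"gap"` (default, `k - 1` per run) or `"run"` (`k` per run of
#'   at least two).
#' @return Number of non-therapeutic days.
#' @examples
#' observed_ntt(c(1, 0, 0, 1)) # 1
#' observed_ntt(c(1, 0, 1, 0, 1)) # 0
#' @export
observed_ntt <- function(states, rule = c("gap", "run")) {
  rule <- match.arg(rule)
  if (is.data.frame(states)) states <- states$state
  assert_that(length(states) > 0, "state series is empty")
  assert_that(all(states %in% c(0, 1)), "states must be 0/1")
  r <- rle(as.integer(states))
  zeros <- r$lengths[r$values == 0]
  if (rule == "gap") sum(pmax(zeros - 1L, 0L)) else sum(zeros[zeros >= 2])
}

#' Simulate a two-state Markov chain of daily states
#'
#' @param p01 Probability of moving 0 -> 1 (re-initiation); scalar or one
#'   value per day.
#' @param p10 Probability of moving 1 -> 0 (discontinuation); scalar or one
#'   value per day.
#' @param n_days Chain length.
#' @param initial_state State assumed before day 1 (default 1).
#' @return Integer vector of daily states, length `n_days`.
#' @export
simulate_chain <- function(p01, p10, n_days, initial_state = 1L) {
  assert_that(all(p01 >= 0 & p01 <= 1) && all(p10 >= 0 & p10 <= 1),
              "transition probabilities must lie in [0, 1]")
  assert_that(initial_state %in% c(0L, 1L), "initial_state must be 0 or 1")
  p01 <- rep_len(p01, n_days)
  p10 <- rep_len(p10, n_days)
  drop(sim_states_matrix(matrix(p01, ncol = 1), matrix(p10, ncol = 1), initial_state))
}

# Vectorized chain simulation: p01_mat/p10_mat are n_days x n_chains; NA
# entries mark unobserved days (ragged follow-up) and yield NA states.
sim_states_matrix <- function(p01_mat, p10_mat, initial_state = 1L) {
  n_days <- nrow(p01_mat); n_chains <- ncol(p01_mat)
  states <- matrix(NA_integer_, n_days, n_chains)
  cur <- rep(as.integer(initial_state), n_chains)
  for (d in seq_len(n_days)) {
    p_take <- ifelse(cur == 0L, p01_mat[d, ], 1 - p10_mat[d, ])
    nxt <- as.integer(stats::runif(n_chains) < p_take)
    obs <- !is.na(p_take)
    states[d, obs] <- nxt[obs]
    cur[obs] <- nxt[obs]
  }
  states
}

#' Model-predicted non-therapeutic time
#'
#' Mean NTT over independent Markov chains simulated from one transition
#' matrix, the stochastic-noise-averaging device used in the observed-versus-
#' predicted NTT diagnostic (100 chains per subject by default).
#'
#' @inheritParams simulate_chain
#' @inheritParams observed_ntt
#' @param reps Number of simulated chains (default 100).
#' @return Mean NTT (days) across replicates.
#' @export
predicted_ntt <- function(p01, p10, n_days, reps = 100, initial_state = 1L,
                          rule = c("gap", "run")) {
  rule <- match.arg(rule)
  assert_that(reps >= 1, "reps must be at least 1")
  p01_mat <- matrix(rep_len(p01, n_days), n_days, reps)
  p10_mat <- matrix(rep_len(p10, n_days), n_days, reps)
  states <- sim_states_matrix(p01_mat, p10_mat, initial_state)
  mean(apply(states, 2, observed_ntt, rule = rule))
}

#' Observed-versus-predicted NTT diagnostic
#'
#' For every subject, computes the observed NTT from the data and the mean
#' NTT over `reps` Markov chains simulated from the subject's empirical-Bayes
#' transition matrix, plus the correlation between the two across subjects —
#' the scatter used to judge whether a model reproduces individual
#' non-adherence patterns. Works for both the Markov fit and the Bernoulli
#' comparator (whose implied matrix has next state independent of the current
#' one).
#'
#' @param fit A `markov_fit` or `bernoulli_fit`.
#' @param states Per-day tibble (`subject_id`, `day`, `state`) the model was
#'   fitted to.
#' @param reps Chains per subject (default 100).
#' @param seed Optional integer seed for reproducible simulation.
#' @inheritParams observed_ntt
#' @return An object of class `ntt_diagnostic`: a list with `summary` (tibble
#'   `subject_id`, `observed_ntt`, `predicted_mean_ntt`, `n_days`,
#'   `n_replicates`) and `correlation` (Pearson, across subjects).
#' @export
ntt_diagnostic <- function(fit, states, reps = 100, seed = NULL,
                           rule = c("gap", "run")) {
  rule <- match.arg(rule)
  ebm <- empirical_bayes_matrices(fit)
  obs <- states |>
    dplyr::arrange(.data$subject_id, .data$day) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(observed_ntt = observed_ntt(.data$state, rule = rule),
                     n_days = dplyr::n(), .groups = "drop")
  df <- dplyr::inner_join(ebm, obs, by = "subject_id")
  pred <- with_seed_maybe(seed, purrr::pmap_dbl(
    list(df$p01, df$p10, df$n_days),
    function(p01, p10, nd) predicted_ntt(p01, p10, nd, reps = reps, rule = rule)
  ))
  summary <- tibble::tibble(subject_id = df$subject_id,
                            observed_ntt = df$observed_ntt,
                            predicted_mean_ntt = pred,
                            n_days = df$n_days,
                            n_replicates = reps)
  corr <- if (stats::sd(summary$observed_ntt) > 0 && stats::sd(pred) > 0) {
    stats::cor(summary$observed_ntt, pred)
  } else NA_real_
  structure(list(summary = summary, correlation = corr, model = class(fit)[1]),
            class = "ntt_diagnostic")
}

#' @export
print.ntt_diagnostic <- function(x, ...) {
  cat(sprintf("Observed vs predicted NTT (%s, %d subjects, %d chains/subject)\n",
              x$model, nrow(x$summary), x$summary$n_replicates[1]))
  cat(sprintf("  correlation: %.3f\n", x$correlation))
  invisible(x)
}

#' Replicate transition-count predictive check
#'
#' Simulates every subject's daily series afresh from the fitted model (same
#' follow-up length, same per-day covariates, empirical-Bayes individual
#' matrices, initial state as configured) and tallies the four transition
#' types, repeating `n_reps` times. Comparing the replicate columns with the
#' observed column shows whether a model reproduces the transition mix; a
#' coin-flip model overpredicts the [10]/[01] switches on persistent data.
#'
#' @param fit A `markov_fit` or `bernoulli_fit`.
#' @param transitions The transition tibble the model was fitted to (supplies
#'   follow-up lengths and per-day covariate vectors).
#' @param n_reps Number of simulation replicates (default 5).
#' @param seed Optional integer seed.
#' @param initial_state State assumed before each subject's day 1 (default 1).
#' @return A tibble with rows `[11]`, `[10]`, `[01]`, `[00]` and columns
#'   `observed`, `sim_1` ... `sim_<n_reps>`; every column sums to the observed
#'   total number of transitions.
#' @export
replicate_transition_counts <- function(fit, transitions, n_reps = 5, seed = NULL,
                                        initial_state = 1L) {
  prob <- per_day_probabilities(fit, transitions)
  mats <- day_by_subject(prob, transitions)
  sims <- with_seed_maybe(seed, lapply(seq_len(n_reps), function(r) {
    st <- sim_states_matrix(mats$p01, mats$p10, initial_state)
    count_state_matrix(st, initial_state)
  }))
  obs_counts <- count_transitions(transitions)
  out <- tibble::tibble(transition = c("11", "10", "01", "00"))
  out$observed <- obs_counts$n[match(out$transition, as.character(obs_counts$transition))]
  for (r in seq_len(n_reps)) out[[paste0("sim_", r)]] <- sims[[r]][out$transition]
  out
}

# Per-row (subject-day) transition probabilities at EBE random effects.
per_day_probabilities <- function(fit, transitions) {
  if (inherits(fit, "bernoulli_fit")) {
    df <- dplyr::left_join(transitions, fit$ebe, by = "subject_id")
    p1 <- expit(fit$theta1 + design_lp(df, fit$beta) + df$eta)
    return(tibble::tibble(subject_id = df$subject_id, day = df$day,
                          p01 = p1, p10 = 1 - p1))
  }
  df <- dplyr::left_join(transitions, fit$ebe, by = "subject_id")
  l1 <- fit$params$theta1 + design_lp(df, fit$params$beta01) + df$eta_p01
  l2 <- fit$params$theta2 + design_lp(df, fit$params$beta10) + df$eta_p10
  tibble::tibble(subject_id = df$subject_id, day = df$day,
                 p01 = expit(l1), p10 = expit(l2))
}

# Reshape per-row probabilities into n_days x n_subjects matrices (NA-padded
# for ragged follow-up), ordered by day within subject.
day_by_subject <- function(prob, transitions) {
  prob <- dplyr::arrange(prob, .data$subject_id, .data$day)
  subjects <- unique(prob$subject_id)
  lens <- tabulate(match(prob$subject_id, subjects))
  n_days <- max(lens)
  idx <- cbind(unlist(lapply(lens, seq_len)), rep(seq_along(subjects), lens))
  p01 <- p10 <- matrix(NA_real_, n_days, length(subjects))
  p01[idx] <- prob$p01
  p10[idx] <- prob$p10
  list(p01 = p01, p10 = p10, subjects = subjects)
}

count_state_matrix <- function(states, initial_state) {
  n_days <- nrow(states)
  prev <- rbind(matrix(as.integer(initial_state), 1, ncol(states)),
                states[-n_days, , drop = FALSE])
  obs <- !is.na(states)
  lab <- paste0(prev[obs], states[obs])
  cnt <- table(factor(lab, levels = c("11", "10", "01", "00")))
  stats::setNames(as.integer(cnt), names(cnt))
}
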