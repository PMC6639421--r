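# Shared fixtures, built in code at test time.

# Small cohort with a mid-window follow-up switch; used across modules.
small_spec <- function(n_subjects = 60, n_days = 60, ...) {
  cohort_spec(n_subjects = n_subjects, n_days = n_days,
              followup_switch_day = ceiling(n_days / 2), ...)
}

# Transitions + truth from a generated cohort, bypassing the file layer.
cohort_transitions <- function(cohort) {
  covs <- cohort$covariates[, setdiff(names(cohort$covariates), "sexrisk")]
  daily <- resolve_covariates(cohort$truth$states, covs, cohort$covariate_intervals)
  build_transitions(daily)
}

# Per-day state tibble for one subject from a plain 0/1 vector.
states_tbl <- function(states, subject_id = "S1", start = as.Date("2015-01-01")) {
  tibble::tibble(subject_id = subject_id,
                 date = start + seq_along(states) - 1,
                 day = seq_along(states),
                 state = as.integer(states))
}

# Event log tibble from per-day states (one 09:00 opening per taken day).
events_from_states <- function(st) {
  taken <- st[st$state == 1L, ]
  tibble::tibble(subject_id = taken$subject_id,
                 timestamp = as.POSIXct(taken$date, tz = "UTC") + 9 * 3600)
}

windows_for <- function(st) {
  st |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(start_date = min(date), end_date = max(date), .groups = "drop")
}

# Simple homogeneous-cohort transitions from known (p01, p10), no covariates.
simulate_transitions <- function(n_subjects, n_days, p01, p10, seed,
                                 omega_sq = c(0, 0), theta = NULL) {
  withr::with_seed(seed, {
    pars <- theta %||% markov_params(qlogis(p01), qlogis(p10), omega_sq = omega_sq)
    rows <- lapply(seq_len(n_subjects), function(i) {
      eta <- stats::rnorm(2, 0, sqrt(pars$omega_sq))
      tp <- transition_probabilities(pars, eta = eta)
      st <- simulate_chain(tp[["p01"]], tp[["p10"]], n_days)
      states_tbl(st, sprintf("S%03d", i))
    })
    build_transitions(dplyr::bind_rows(rows))
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
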