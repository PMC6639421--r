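#' Specification of a synthetic adherence cohort
#'
#' Defines the generative model for a MEMS-style cohort: number of subjects
#' and follow-up days, covariate prevalences, true Markov parameters, and
#' event-time jitter. The defaults emulate a PrEP demonstration cohort of 920
#' subjects followed 360 days: covariate prevalences match the published
#' demographic mix (male 65% / female 35%, age >= 25 80%, sex-risk
#' no-sex/100%-condom/<100%-condom 4%/34%/62%, partner on ART >= 6 months 52%,
#' wants relationship to succeed 88%, problem alcohol use 20%), the covariate
#' log odds ratios are the published effect estimates, being beyond six months
#' of follow-up is a deterministic time-varying indicator switching at study
#' day 183, and the intercepts are calibrated so the cohort-average transition
#' probabilities are P01 ~ 0.28 and P10 ~ 0.11 (about 75% stationary
#' adherence, [11] dominating the transition mix). Random-effect variance is
#' 0.5 per logit.
#'
#' @param n_subjects,n_days Cohort size and follow-up length.
#' @param prevalence Named list of Bernoulli prevalences for the binary
#'   covariates and a length-3 probability vector `sexrisk`
#'   (no-sex, 100%-condom, <100%-condom).
#' @param params True [markov_params()] driving the chains.
#' @param followup_switch_day Study day on which the follow-up > 6 months
#'   indicator switches from 0 to 1 for every subject (default 183); `NA`
#'   disables the covariate.
#' @param start_date Calendar date of every subject's day 1.
#' @param jitter_hours Opening clock times are drawn uniformly in this window
#'   (hours; default 06:00-22:00). Immaterial to the analysis; exercises the
#'   timestamp parser.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 920, n_days = 360,
                        prevalence = list(female = 0.35, age25 = 0.80,
                                          art6m = 0.52, wants = 0.88,
                                          alcohol = 0.20,
                                          sexrisk = c(0.04, 0.34, 0.62)),
                        params = default_true_params(),
                        followup_switch_day = 183,
                        start_date = as.Date("2015-01-01"),
                        jitter_hours = c(6, 22)) {
  assert_that(n_subjects >= 1 && n_days >= 1, "n_subjects and n_days must be >= 1")
  binary <- setdiff(names(prevalence), "sexrisk")
  pv <- unlist(prevalence[binary])
  assert_that(all(pv >= 0 & pv <= 1), "prevalences must lie in [0, 1]")
  assert_that(abs(sum(prevalence$sexrisk) - 1) < 1e-8,
              "sexrisk prevalences must sum to 1")
  structure(list(n_subjects = n_subjects, n_days = n_days,
                 prevalence = prevalence, params = params,
                 followup_switch_day = followup_switch_day,
                 start_date = as.Date(start_date), jitter_hours = jitter_hours),
            class = "cohort_spec")
}

#' True generating parameters anchored to the published effect sizes
#'
#' Covariate log odds ratios on the two transition logits are the published
#' point estimates: on P10, age >= 25 (OR 0.61), female sex (0.67), partner on
#' ART >= 6 months (1.34), wants relationship to succeed (0.79), follow-up > 6
#' months (1.25), problem alcohol (1.16), 100% condom use vs no sex (0.84) and
#' <100% condom use vs no sex (0.69); on P01, partner on ART (0.86), wants
#' relationship (1.45), follow-up (0.80), alcohol (0.63) and <100% condom use
#' (1.21). Intercepts theta1 = -1.11, theta2 = -1.35 are fixed so the
#' cohort-average profile sits at P01 ~ 0.28, P10 ~ 0.11.
#'
#' @param omega_sq Random-effect variance per logit (default 0.5).
#' @return A [markov_params()] object.
#' @export
default_true_params <- function(omega_sq = c(0.5, 0.5)) {
  markov_params(
    theta1 = -1.11, theta2 = -1.35,
    beta01 = c(art6m = log(0.86), wants = log(1.45), followup6m = log(0.80),
               alcohol = log(0.63), condom_lt100 = log(1.21)),
    beta10 = c(age25 = log(0.61), female = log(0.67), art6m = log(1.34),
               wants = log(0.79), followup6m = log(1.25), alcohol = log(1.16),
               condom100 = log(0.84), condom_lt100 = log(0.69)),
    omega_sq = omega_sq, random = "separate"
  )
}

#' Draw a synthetic covariate table
#'
#' Independent draws per subject: Bernoulli indicators at the configured
#' prevalences and a three-level sex-risk covariate coded as two indicators
#' (`condom100`, `condom_lt100`) against the no-sex reference, with the
#' original factor kept in `sexrisk`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return A tibble, one row per subject.
#' @export
generate_covariates <- function(spec, seed = NULL) {
  with_seed_maybe(seed, {
    n <- spec$n_subjects
    out <- tibble::tibble(subject_id = sprintf("S%04d", seq_len(n)))
    for (cv in setdiff(names(spec$prevalence), "sexrisk")) {
      out[[cv]] <- as.numeric(stats::runif(n) < spec$prevalence[[cv]])
    }
    lev <- c("no_sex", "condom100", "condom_lt100")
    risk <- sample(lev, n, replace = TRUE, prob = spec$prevalence$sexrisk)
    out$sexrisk <- factor(risk, levels = lev)
    out$condom100 <- as.numeric(risk == "condom100")
    out$condom_lt100 <- as.numeric(risk == "condom_lt100")
    out
  })
}

followup_intervals <- function(spec) {
  if (is.na(spec$followup_switch_day)) return(NULL)
  sw <- spec$followup_switch_day
  assert_that(sw >= 1, "followup_switch_day must be >= 1")
  # a switch beyond the window simply never happens: indicator stays 0
  if (sw > spec$n_days) sw <- spec$n_days + 1
  iv <- tibble::tibble(
    subject_id = ".all",
    covariate = "followup6m",
    value = c(0, 1),
    interval_start_day = c(1, sw),
    interval_end_day = c(sw - 1, spec$n_days)
  )
  iv[iv$interval_start_day <= iv$interval_end_day, ]
}

#' Generate a synthetic MEMS-style cohort
#'
#' Draws covariates, subject random effects and daily adherence chains from
#' the configured generative Markov model, then emits the observable files a
#' real study would yield — an event log with one jittered opening timestamp
#' per dose-taking day, a covariate table, a time-varying covariate interval
#' table, and a follow-up window file — alongside the hidden truth (random
#' effects and daily states) kept separately for parameter-recovery checks.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed; generation is a pure function of
#'   `(spec, seed)`.
#' @return A list of class `synthetic_cohort` with elements `events`,
#'   `covariates`, `covariate_intervals`, `windows`, and `truth` (list:
#'   `params`, `eta` tibble, `states` per-day tibble).
#' @export
generate_cohort <- function(spec, seed = NULL) {
  with_seed_maybe(seed, {
    covs <- generate_covariates(spec)
    n <- spec$n_subjects
    om <- spec$params$omega_sq
    eta1 <- stats::rnorm(n, 0, sqrt(om[1]))
    eta2 <- if (spec$params$random == "shared") eta1 else stats::rnorm(n, 0, sqrt(om[2]))
    intervals <- followup_intervals(spec)
    windows <- tibble::tibble(subject_id = covs$subject_id,
                              start_date = spec$start_date,
                              end_date = spec$start_date + (spec$n_days - 1))
    grid <- tidyr::expand_grid(subject_id = covs$subject_id, day = seq_len(spec$n_days)) |>
      dplyr::mutate(date = spec$start_date + .data$day - 1)
    daily <- resolve_covariates(grid, covs[, setdiff(names(covs), "sexrisk")], intervals)
    l1 <- spec$params$theta1 + design_lp(daily, spec$params$beta01) + eta1[match(daily$subject_id, covs$subject_id)]
    l2 <- spec$params$theta2 + design_lp(daily, spec$params$beta10) + eta2[match(daily$subject_id, covs$subject_id)]
    mats <- day_by_subject(tibble::tibble(subject_id = daily$subject_id, day = daily$day,
                                          p01 = expit(l1), p10 = expit(l2)),
                           NULL)
    st <- sim_states_matrix(mats$p01, mats$p10, initial_state = 1L)
    states <- tibble::tibble(
      subject_id = rep(mats$subjects, each = spec$n_days),
      date = rep(spec$start_date + seq_len(spec$n_days) - 1, n),
      day = rep(seq_len(spec$n_days), n),
      state = as.integer(st[cbind(rep(seq_len(spec$n_days), n),
                                  rep(seq_len(n), each = spec$n_days))])
    )
    taken <- states[states$state == 1L, ]
    hrs <- stats::runif(nrow(taken), spec$jitter_hours[1], spec$jitter_hours[2])
    events <- tibble::tibble(
      subject_id = taken$subject_id,
      timestamp = as.POSIXct(taken$date, tz = "UTC") + round(hrs * 3600)
    )
    structure(list(
      events = events,
      covariates = covs,
      covariate_intervals = intervals,
      windows = windows,
      truth = list(params = spec$params,
                   eta = tibble::tibble(subject_id = covs$subject_id,
                                        eta_p01 = eta1, eta_p10 = eta2),
                   states = states),
      spec = spec
    ), class = "synthetic_cohort")
  })
}

#' Make a subject-constant covariate time-varying
#'
#' Replaces a 0/1 covariate by a within-subject switch: the indicator is 0
#' before each subject's switch day and takes the subject's original value
#' from the switch day onward (a switch on day 1 reproduces the
#' subject-constant coding). The daily chains are re-simulated under the new
#' per-day probabilities with the same subject random effects.
#'
#' @param cohort A `synthetic_cohort`.
#' @param covariate Name of a 0/1 covariate column to convert.
#' @param switch_day Scalar or per-subject vector of 1-based switch days.
#' @param seed Optional integer seed for the re-simulation.
#' @return A new `synthetic_cohort` with updated interval table, events and
#'   truth.
#' @export
inject_timevarying <- function(cohort, covariate, switch_day, seed = NULL) {
  spec <- cohort$spec
  covs <- cohort$covariates
  assert_that(covariate %in% names(covs), paste0("unknown covariate: ", covariate))
  sw <- rep_len(switch_day, spec$n_subjects)
  assert_that(all(sw >= 1 & sw <= spec$n_days), "switch day outside the window")
  iv_new <- purrr::map_dfr(seq_len(spec$n_subjects), function(i) {
    v <- covs[[covariate]][i]
    out <- tibble::tibble(subject_id = covs$subject_id[i], covariate = covariate,
                          value = c(0, v),
                          interval_start_day = c(1, sw[i]),
                          interval_end_day = c(sw[i] - 1, spec$n_days))
    out[out$interval_start_day <= out$interval_end_day, ]
  })
  intervals <- dplyr::bind_rows(cohort$covariate_intervals, iv_new)
  covs_wide <- covs[, setdiff(names(covs), c("sexrisk", covariate))]
  with_seed_maybe(seed, {
    grid <- tidyr::expand_grid(subject_id = covs$subject_id, day = seq_len(spec$n_days)) |>
      dplyr::mutate(date = spec$start_date + .data$day - 1)
    daily <- resolve_covariates(grid, covs_wide, intervals)
    eta <- cohort$truth$eta
    i1 <- match(daily$subject_id, eta$subject_id)
    l1 <- spec$params$theta1 + design_lp(daily, spec$params$beta01) + eta$eta_p01[i1]
    l2 <- spec$params$theta2 + design_lp(daily, spec$params$beta10) + eta$eta_p10[i1]
    mats <- day_by_subject(tibble::tibble(subject_id = daily$subject_id, day = daily$day,
                                          p01 = expit(l1), p10 = expit(l2)), NULL)
    st <- sim_states_matrix(mats$p01, mats$p10, initial_state = 1L)
    n <- spec$n_subjects
    states <- tibble::tibble(
      subject_id = rep(mats$subjects, each = spec$n_days),
      date = rep(spec$start_date + seq_len(spec$n_days) - 1, n),
      day = rep(seq_len(spec$n_days), n),
      state = as.integer(st[cbind(rep(seq_len(spec$n_days), n),
                                  rep(seq_len(n), each = spec$n_days))])
    )
    taken <- states[states$state == 1L, ]
    hrs <- stats::runif(nrow(taken), spec$jitter_hours[1], spec$jitter_hours[2])
    cohort$events <- tibble::tibble(
      subject_id = taken$subject_id,
      timestamp = as.POSIXct(taken$date, tz = "UTC") + round(hrs * 3600)
    )
    cohort$covariates <- covs[, setdiff(names(covs), covariate)]
    cohort$covariate_intervals <- intervals
    cohort$truth$states <- states
    cohort
  })
}

#' Write / read the observable files of a synthetic cohort
#'
#' `write_cohort()` emits exactly the delimited formats the readers consume:
#' `events.csv`, `covariates.csv`, `covariate_intervals.csv` (when present),
#' `windows.csv`, plus `truth.json` with the generating parameters.
#' `read_cohort()` loads the observable files back through [read_event_log()],
#' [read_covariate_table()] and [read_window_file()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param max_days Passed to [read_window_file()] (default keeps the windows
#'   as written).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a list
#'   `events`, `covariates`, `covariate_intervals`, `windows`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ev <- cohort$events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(ev, file.path(dir, "events.csv"))
  covs <- cohort$covariates
  covs$sexrisk <- NULL
  readr::write_csv(covs, file.path(dir, "covariates.csv"))
  if (!is.null(cohort$covariate_intervals)) {
    readr::write_csv(cohort$covariate_intervals, file.path(dir, "covariate_intervals.csv"))
  }
  readr::write_csv(cohort$windows, file.path(dir, "windows.csv"))
  tp <- cohort$truth$params
  truth <- list(theta1 = tp$theta1, theta2 = tp$theta2,
                beta01 = as.list(tp$beta01), beta10 = as.list(tp$beta10),
                omega_sq = tp$omega_sq, random = tp$random)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, max_days = Inf) {
  iv_path <- file.path(dir, "covariate_intervals.csv")
  list(
    events = read_event_log(file.path(dir, "events.csv")),
    covariates = read_covariate_table(file.path(dir, "covariates.csv")),
    covariate_intervals = if (file.exists(iv_path)) read_covariate_table(iv_path) else NULL,
    windows = read_window_file(file.path(dir, "windows.csv"), max_days = max_days)
  )
}
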