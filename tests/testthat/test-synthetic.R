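test_that("covariate draws hit the configured prevalences", {
  spec <- cohort_spec(n_subjects = 20000, n_days = 5, followup_switch_day = NA)
  covs <- generate_covariates(spec, seed = 1)
  for (cv in c("female", "age25", "art6m", "wants", "alcohol")) {
    p <- spec$prevalence[[cv]]
    se <- sqrt(p * (1 - p) / 20000)
    expect_lt(abs(mean(covs[[cv]]) - p), 3 * se)
  }
  risk <- table(covs$sexrisk) / 20000
  for (i in 1:3) {
    p <- spec$prevalence$sexrisk[i]
    expect_lt(abs(risk[[i]] - p), 3 * sqrt(p * (1 - p) / 20000))
  }
  # degenerate prevalence gives an all-zero column
  covs0 <- generate_covariates(cohort_spec(n_subjects = 50, prevalence = list(
    female = 0, age25 = 1, art6m = 0.5, wants = 0.5, alcohol = 0.5,
    sexrisk = c(1, 0, 0))), seed = 2)
  expect_true(all(covs0$female == 0))
  expect_true(all(covs0$age25 == 1))
})

test_that("generation is a pure function of spec and seed", {
  spec <- small_spec(n_subjects = 15, n_days = 20)
  a <- generate_cohort(spec, seed = 9)
  b <- generate_cohort(spec, seed = 9)
  expect_identical(a$events, b$events)
  expect_identical(a$truth$eta, b$truth$eta)
  c <- generate_cohort(spec, seed = 10)
  expect_false(identical(a$events, c$events))
})

test_that("the event log is consistent with the hidden states", {
  co <- generate_cohort(small_spec(n_subjects = 12, n_days = 15), seed = 21)
  ev_days <- co$events |>
    dplyr::mutate(date = as.Date(timestamp)) |>
    dplyr::count(subject_id, date)
  expect_true(all(ev_days$n == 1)) # exactly one opening per dose-taking day
  truth1 <- co$truth$states[co$truth$states$state == 1, c("subject_id", "date")]
  expect_equal(nrow(ev_days), nrow(truth1))
  expect_equal(dplyr::anti_join(truth1, ev_days, by = c("subject_id", "date")) |> nrow(), 0)
})

test_that("a degenerate spec yields an all-adherent cohort with a full event log", {
  pars <- markov_params(theta1 = 0, theta2 = -40, omega_sq = c(0, 0))
  spec <- cohort_spec(n_subjects = 8, n_days = 12, params = pars,
                      followup_switch_day = NA)
  co <- generate_cohort(spec, seed = 3)
  expect_equal(sum(co$truth$states$state), 8 * 12)
  expect_equal(nrow(co$events), 8 * 12)
})

test_that("pooled transition frequencies of a large zero-variance cohort match the truth", {
  pars <- markov_params(qlogis(0.3), qlogis(0.12), omega_sq = c(0, 0))
  spec <- cohort_spec(n_subjects = 600, n_days = 120, params = pars,
                      followup_switch_day = NA)
  co <- generate_cohort(spec, seed = 31)
  tr <- build_transitions(co$truth$states)
  cnt <- count_transitions(tr)
  n <- setNames(cnt$n, as.character(cnt$transition))
  p01_hat <- n[["01"]] / (n[["01"]] + n[["00"]])
  p10_hat <- n[["10"]] / (n[["10"]] + n[["11"]])
  expect_lt(abs(p01_hat - 0.3), 3 * sqrt(0.3 * 0.7 / (n[["01"]] + n[["00"]])))
  expect_lt(abs(p10_hat - 0.12), 3 * sqrt(0.12 * 0.88 / (n[["10"]] + n[["11"]])))
})

test_that("the follow-up indicator switches at the configured day", {
  spec <- cohort_spec(n_subjects = 4, n_days = 360, followup_switch_day = 183)
  co <- generate_cohort(spec, seed = 41)
  daily <- resolve_covariates(co$truth$states,
                              co$covariates[, setdiff(names(co$covariates), "sexrisk")],
                              co$covariate_intervals)
  one <- daily[daily$subject_id == daily$subject_id[1], ]
  expect_equal(sum(one$followup6m == 0), 182)
  expect_equal(sum(one$followup6m == 1), 178)
  expect_true(all(one$followup6m[one$day >= 183] == 1))
})

test_that("observable files round-trip and feed the full pipeline to recovery", {
  spec <- small_spec(n_subjects = 150, n_days = 100)
  co <- generate_cohort(spec, seed = 47)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  obs <- read_cohort(dir)
  expect_equal(nrow(obs$events), nrow(co$events))
  st <- daily_states(obs$events, obs$windows)
  truth_states <- co$truth$states[order(co$truth$states$subject_id, co$truth$states$day), ]
  expect_equal(st$state, truth_states$state)
  daily <- resolve_covariates(st, obs$covariates, obs$covariate_intervals)
  tr <- build_transitions(daily)
  fit <- fit_markov(tr, p01 = names(spec$params$beta01), p10 = names(spec$params$beta10))
  truth <- c(spec$params$theta1, spec$params$beta01, spec$params$theta2, spec$params$beta10)
  expect_true(mean(abs(fit$coefficients$estimate - truth) < 3 * fit$coefficients$se) >= 14 / 15)
})

test_that("injecting a time-varying switch changes coding and respects boundaries", {
  spec <- small_spec(n_subjects = 30, n_days = 40)
  co <- generate_cohort(spec, seed = 53)
  tv <- inject_timevarying(co, "art6m", switch_day = 21, seed = 54)
  expect_false("art6m" %in% names(tv$covariates))
  iv <- tv$covariate_intervals[tv$covariate_intervals$covariate == "art6m", ]
  expect_equal(sort(unique(iv$interval_start_day)), c(1, 21))
  daily <- resolve_covariates(tv$truth$states,
                              tv$covariates[, setdiff(names(tv$covariates), "sexrisk")],
                              tv$covariate_intervals)
  expect_true(all(daily$art6m[daily$day < 21] == 0))

  # switch on day 1 reproduces the subject-constant coding
  tv1 <- inject_timevarying(co, "art6m", switch_day = 1, seed = 55)
  daily1 <- resolve_covariates(tv1$truth$states,
                               tv1$covariates[, setdiff(names(tv1$covariates), "sexrisk")],
                               tv1$covariate_intervals)
  per_subj <- daily1 |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(n_vals = dplyr::n_distinct(art6m), .groups = "drop")
  expect_true(all(per_subj$n_vals == 1))

  expect_error(inject_timevarying(co, "art6m", switch_day = 99), "outside the window")
})

test_that("a negative post-switch effect on P01 lowers the re-initiation frequency", {
  pars <- markov_params(qlogis(0.35), qlogis(0.12),
                        beta01 = c(art6m = -0.7), beta10 = c(art6m = 0),
                        omega_sq = c(0, 0))
  spec <- cohort_spec(n_subjects = 400, n_days = 120, params = pars,
                      followup_switch_day = NA,
                      prevalence = list(female = .5, age25 = .5, art6m = 1,
                                        wants = .5, alcohol = .5,
                                        sexrisk = c(1, 0, 0)))
  co <- generate_cohort(spec, seed = 57)
  tv <- inject_timevarying(co, "art6m", switch_day = 61, seed = 58)
  tr <- build_transitions(tv$truth$states)
  rate01 <- function(d) {
    cnt <- count_transitions(d)
    n <- setNames(cnt$n, as.character(cnt$transition))
    n[["01"]] / (n[["01"]] + n[["00"]])
  }
  expect_gt(rate01(tr[tr$day < 61, ]), rate01(tr[tr$day >= 61, ]))
})
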