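test_that("with no random effects the fit reproduces the closed-form transition MLE", {
  tr <- simulate_transitions(20, 30, 0.3, 0.12, seed = 31)
  cnt <- count_transitions(tr)
  n <- setNames(cnt$n, as.character(cnt$transition))
  fit <- fit_markov(tr, random = "none")
  expect_equal(plogis(fit$params$theta1), n[["01"]] / (n[["01"]] + n[["00"]]),
               tolerance = 1e-5)
  expect_equal(plogis(fit$params$theta2), n[["10"]] / (n[["10"]] + n[["11"]]),
               tolerance = 1e-5)
})

test_that("the Bernoulli fit with no random effects is the empirical dose-taking fraction", {
  tr <- simulate_transitions(15, 25, 0.4, 0.2, seed = 32)
  fit <- fit_bernoulli(tr, random = "none")
  expect_equal(plogis(fit$theta1), mean(tr$state), tolerance = 1e-5)
})

test_that("parameters are recovered within 3 SE on a seeded synthetic cohort", {
  spec <- small_spec(n_subjects = 250, n_days = 120)
  co <- generate_cohort(spec, seed = 77)
  tr <- cohort_transitions(co)
  fit <- fit_markov(tr, p01 = names(spec$params$beta01), p10 = names(spec$params$beta10))
  expect_true(fit$converged)
  truth <- c(spec$params$theta1, spec$params$beta01, spec$params$theta2, spec$params$beta10)
  z <- abs(fit$coefficients$estimate - truth) / fit$coefficients$se
  # 15 simultaneous z-scores: all moderate, and nearly all within 3 SE
  expect_true(all(z < 4))
  expect_gte(mean(z < 3), 13 / 15)
})

test_that("refitting from the optimum reproduces the objective", {
  tr <- simulate_transitions(25, 30, 0.3, 0.15, seed = 41, omega_sq = c(0.4, 0.4))
  fit <- fit_markov(tr)
  fit2 <- fit_markov(tr, start = fit$params)
  expect_equal(fit2$neg2ll, fit$neg2ll, tolerance = 1e-6)
})

test_that("the Markov model beats the Bernoulli model on persistent data and matches it on iid data", {
  # strongly persistent chains: p01 + p10 far from 1
  tr <- simulate_transitions(60, 60, 0.2, 0.08, seed = 51, omega_sq = c(0.3, 0.3))
  mk <- fit_markov(tr)
  bn <- fit_bernoulli(tr)
  expect_gt(bn$neg2ll - mk$neg2ll, 100)
  expect_equal(compare_models(mk, bn)$drop_vs_bernoulli[2], bn$neg2ll - mk$neg2ll)

  # iid chains: p01 = 1 - p10 = P(1); next state independent of previous
  tr2 <- simulate_transitions(60, 60, 0.7, 0.3, seed = 52, omega_sq = c(0, 0))
  mk2 <- fit_markov(tr2, random = "none")
  bn2 <- fit_bernoulli(tr2, random = "none")
  expect_equal(plogis(mk2$params$theta1), plogis(bn2$theta1), tolerance = 0.03)
  expect_equal(plogis(-mk2$params$theta2), plogis(bn2$theta1), tolerance = 0.03)
})

test_that("Wald odds ratios follow the closed form and bracket the estimate", {
  fit <- list(coefficients = tibble::tibble(
    term = c("(Intercept)", "x", "y"), parameter = c("p01", "p01", "p10"),
    estimate = c(-1, 0, log(0.61)), se = c(0.05, 0.1, 0.12)
  ))
  class(fit) <- "markov_fit"
  ors <- odds_ratios(fit)
  expect_equal(ors$or[1], 1)
  expect_equal(ors$ci_low[1], exp(-1.96 * 0.1), tolerance = 1e-10)
  expect_equal(ors$ci_low[1], 0.822, tolerance = 1e-3)
  expect_equal(ors$ci_high[1], 1.216, tolerance = 1e-3)
  expect_equal(ors$or[2], 0.61)
  expect_true(all(ors$ci_low <= ors$or & ors$or <= ors$ci_high))
})

test_that("empirical-Bayes matrices collapse to the population matrix when variance is zero", {
  tr <- simulate_transitions(10, 20, 0.3, 0.15, seed = 61)
  fit <- fit_markov(tr, random = "none")
  ebm <- empirical_bayes_matrices(fit)
  expect_equal(dplyr::n_distinct(round(ebm$p01, 12)), 1)
  expect_equal(ebm$p01 + ebm$p00, rep(1, nrow(ebm)))
  expect_equal(ebm$p10 + ebm$p11, rep(1, nrow(ebm)))
})

test_that("an all-adherent subject gets a negative discontinuation random effect", {
  rows <- c(lapply(1:10, function(i) {
    withr::with_seed(100 + i, states_tbl(rbinom(30, 1, 0.7), sprintf("M%02d", i)))
  }), list(states_tbl(rep(1, 30), "PERFECT")))
  tr <- build_transitions(dplyr::bind_rows(rows))
  fit <- fit_markov(tr)
  eta_perfect <- fit$ebe$eta_p10[fit$ebe$subject_id == "PERFECT"]
  expect_lt(eta_perfect, 0)
  ebm <- empirical_bayes_matrices(fit)
  expect_lt(ebm$p10[ebm$subject_id == "PERFECT"], plogis(fit$params$theta2))
})

test_that("tidy and glance expose the broom-style surfaces", {
  tr <- simulate_transitions(15, 20, 0.3, 0.2, seed = 71)
  fit <- fit_markov(tr)
  td <- tidy(fit)
  expect_true(all(c("term", "parameter", "estimate", "std.error", "conf.low") %in% names(td)))
  td_or <- tidy(fit, exponentiate = TRUE)
  expect_equal(td_or$estimate, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$n_transitions, 300L)
  expect_equal(gl$neg2ll, fit$neg2ll)
})

test_that("shared random-effect structure fits and is reported as such", {
  tr <- simulate_transitions(30, 30, 0.3, 0.15, seed = 81, omega_sq = c(0.3, 0.3))
  fit <- fit_markov(tr, random = "shared")
  expect_true(fit$converged)
  expect_equal(fit$omega$parameter, "shared")
  expect_equal(fit$ebe$eta_p01, fit$ebe$eta_p10)
})

test_that("agq fitting agrees with laplace on small data", {
  tr <- simulate_transitions(20, 25, 0.35, 0.15, seed = 91, omega_sq = c(0.4, 0.4))
  f_lap <- fit_markov(tr, method = "laplace")
  f_agq <- fit_markov(tr, method = "agq", nodes = 9)
  expect_lt(abs(f_agq$params$theta1 - f_lap$params$theta1), 0.05)
  expect_lt(abs(f_agq$params$theta2 - f_lap$params$theta2), 0.05)
})
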