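# Numerical ODE oracle for the compartment models.
ode_profile <- function(doses, params, times) {
  skip_if_not_installed("deSolve")
  ka <- params$ka
  if (params$n_compartments == 1L) {
    ke <- params$cl / params$v
    rhs <- function(t, y, p) list(c(-ka * y[1], ka * y[1] - ke * y[2]))
    y0 <- c(gut = 0, central = 0)
  } else {
    k <- params$cl / params$v; k12 <- params$q / params$v; k21 <- params$q / params$vp
    # amounts: central gains k21*A_p, loses k12*A_c
    rhs <- function(t, y, p) list(c(
      -ka * y[1],
      ka * y[1] - (k + k12) * y[2] + k21 * y[3],
      k12 * y[2] - k21 * y[3]
    ))
    y0 <- c(gut = 0, central = 0, peripheral = 0)
  }
  ev <- data.frame(var = "gut", time = doses$time, value = doses$amount, method = "add")
  grid <- sort(unique(c(times, doses$time)))
  out <- deSolve::ode(y0, grid, rhs, NULL, events = list(data = ev),
                      rtol = 1e-12, atol = 1e-12)
  conc <- out[match(times, out[, "time"]), "central"] / params$v * 1000
  tibble::tibble(time = times, conc = conc)
}

test_that("adherence chains convert to dosing histories by construction", {
  d <- chain_to_doses(rep(1, 30), dose_time_of_day = 8)
  expect_equal(nrow(d), 30)
  expect_equal(unique(diff(d$time)), 24)
  expect_equal(nrow(chain_to_doses(rep(0, 10))), 0)
  d2 <- chain_to_doses(c(1, 0, 1))
  expect_equal(d2$time, c(8, 56))
})

test_that("no doses give a zero profile and superposition holds", {
  pk <- pk_params(ka = 1, cl = 60, v = 1200)
  times <- seq(0, 96, by = 1)
  expect_true(all(simulate_profile(chain_to_doses(c(0, 0)), pk, times)$conc == 0))

  d1 <- tibble::tibble(time = 8, amount = 300)
  d2 <- tibble::tibble(time = 32, amount = 300)
  both <- dplyr::bind_rows(d1, d2)
  expect_equal(simulate_profile(both, pk, times)$conc,
               simulate_profile(d1, pk, times)$conc + simulate_profile(d2, pk, times)$conc,
               tolerance = 1e-12)
})

test_that("the closed-form profile matches the ODE oracle for both compartment forms", {
  times <- seq(0, 120, by = 0.5)
  doses <- tibble::tibble(time = c(8, 32, 80), amount = c(300, 300, 150))
  withr::with_seed(12, {
    for (i in 1:3) {
      pk1 <- pk_params(ka = runif(1, 0.3, 2), cl = runif(1, 20, 90),
                       v = runif(1, 300, 1500))
      ana <- simulate_profile(doses, pk1, times)
      ode <- ode_profile(doses, pk1, times)
      scale <- max(ode$conc)
      expect_lt(max(abs(ana$conc - ode$conc)) / scale, 1e-6)
    }
    pk2 <- pk_params(ka = 1.1, cl = 50, v = 400, q = 15, vp = 600)
    ana2 <- simulate_profile(doses, pk2, times)
    ode2 <- ode_profile(doses, pk2, times)
    expect_lt(max(abs(ana2$conc - ode2$conc)) / max(ode2$conc), 1e-6)
  })
})

test_that("the absorption-elimination collision uses the analytic limit", {
  # ka == ke exactly: limit formula, continuous in ka
  pk_eq <- pk_params(ka = 0.05, cl = 60, v = 1200) # ke = 0.05 = ka
  pk_near <- pk_params(ka = 0.0500001, cl = 60, v = 1200)
  times <- seq(0, 72, by = 0.5)
  d <- tibble::tibble(time = 0, amount = 300)
  a <- simulate_profile(d, pk_eq, times)$conc
  b <- simulate_profile(d, pk_near, times)$conc
  expect_lt(max(abs(a - b)) / max(a), 1e-4)
})

test_that("profiles are linear in dose and monotone in the dose set", {
  pk <- pk_params(ka = 1, cl = 60, v = 1200)
  times <- seq(0, 10 * 24, by = 1)
  withr::with_seed(8, {
    chain <- rbinom(10, 1, 0.7)
    doses <- chain_to_doses(chain)
    base <- simulate_profile(doses, pk, times)$conc
    double <- simulate_profile(dplyr::mutate(doses, amount = amount * 2), pk, times)$conc
    expect_equal(double, 2 * base, tolerance = 1e-12)
    for (k in seq_len(nrow(doses))) {
      thin <- simulate_profile(doses[-k, ], pk, times)$conc
      expect_true(all(thin <= base + 1e-12))
    }
  })
})

test_that("threshold metrics count strictly-below time by linear interpolation", {
  prof <- tibble::tibble(time = 0:10, conc = rep(100, 11))
  m <- threshold_metrics(prof, threshold = 40)
  expect_equal(m$fraction_below, 0)
  expect_true(is.na(m$first_crossing))

  # constant exactly at the threshold is not strictly below
  at <- tibble::tibble(time = 0:10, conc = rep(40, 11))
  expect_equal(threshold_metrics(at, threshold = 40)$fraction_below, 0)

  # piecewise linear: 80 -> 0 over 0..10 crosses 40 at t = 5
  ramp <- tibble::tibble(time = c(0, 10), conc = c(80, 0))
  m2 <- threshold_metrics(ramp, threshold = 40)
  expect_equal(m2$fraction_below, 0.5)
  expect_equal(m2$first_crossing, 5)
  expect_equal(m2$longest_below, 5)

  # dip below and recover: below between t = 2.5 and t = 7.5
  dip <- tibble::tibble(time = c(0, 5, 10), conc = c(90, -10, 90))
  m3 <- threshold_metrics(dip, threshold = 40)
  expect_equal(m3$fraction_below, 0.5)
  expect_equal(m3$longest_below, 5)
  expect_equal(m3$first_crossing, 2.5)
})

test_that("a dosing gap cannot reduce time below the protection threshold", {
  pk <- pk_defaults()
  times <- seq(0, 30 * 24, by = 1)
  full <- simulate_profile(chain_to_doses(rep(1, 30)), pk, times)
  gap_chain <- c(rep(1, 10), rep(0, 5), rep(1, 15))
  gap <- simulate_profile(chain_to_doses(gap_chain), pk, times)
  expect_gte(threshold_metrics(gap)$fraction_below,
             threshold_metrics(full)$fraction_below)
  expect_gt(threshold_metrics(gap)$fraction_below, 0)
})

test_that("the covariate panel contrasts categories and respects strict mode", {
  pars <- markov_params(qlogis(0.3), qlogis(0.12),
                        beta01 = c(alcohol = log(0.63)),
                        beta10 = c(alcohol = log(1.16)),
                        omega_sq = c(0, 0))
  pan <- covariate_profile_panel(pars, "alcohol", n_days = 20, seed = 5)
  expect_equal(nrow(pan$matrices), 2)
  expect_lt(pan$matrices$p01[2], pan$matrices$p01[1])
  expect_gt(pan$matrices$p10[2], pan$matrices$p10[1])
  pan2 <- covariate_profile_panel(pars, "alcohol", n_days = 20, seed = 5)
  expect_identical(pan$profiles, pan2$profiles)

  # a null covariate yields identical matrices
  pars0 <- markov_params(0, 0, beta01 = c(x = 0), beta10 = c(x = 0))
  pan0 <- covariate_profile_panel(pars0, "x", n_days = 5, seed = 1)
  expect_equal(pan0$matrices$p01[1], pan0$matrices$p01[2])

  expect_error(covariate_profile_panel(pars, "alcohol", strict = TRUE),
               "illustrative")
})

test_that("a category with better transition odds misses stochastically fewer days", {
  pars <- markov_params(qlogis(0.3), qlogis(0.25),
                        beta01 = c(good = 1), beta10 = c(good = -1),
                        omega_sq = c(0, 0))
  tp0 <- transition_probabilities(pars, c(good = 0))
  tp1 <- transition_probabilities(pars, c(good = 1))
  withr::with_seed(31, {
    miss0 <- replicate(200, sum(simulate_chain(tp0[["p01"]], tp0[["p10"]], 60) == 0))
    miss1 <- replicate(200, sum(simulate_chain(tp1[["p01"]], tp1[["p10"]], 60) == 0))
  })
  expect_lt(mean(miss1), mean(miss0))
  expect_lt(quantile(miss1, 0.75), quantile(miss0, 0.75))
})
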