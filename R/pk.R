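#' Pharmacokinetic model parameters
#'
#' Parameters of a linear one- or two-compartment disposition model with
#' first-order absorption, used to translate adherence chains into plasma
#' concentration profiles by superposition of closed-form single-dose
#' solutions. Bioavailability is folded into the apparent clearance and
#' volumes.
#'
#' @param ka First-order absorption rate constant (1/h).
#' @param cl Apparent clearance CL/F (L/h).
#' @param v Apparent central volume V/F (L).
#' @param q,vp Inter-compartmental clearance (L/h) and peripheral volume (L);
#'   supply both for the two-compartment form, omit for one compartment.
#' @param dose Dose per administration (mg; default 300, a
#'   tenofovir-disoproxil-fumarate-sized oral dose).
#' @param illustrative Flag carried on the object; [pk_defaults()] sets it to
#'   mark parameter sets intended for illustration rather than inference.
#' @return A list of class `pk_params`.
#' @export
pk_params <- function(ka, cl, v, q = NULL, vp = NULL, dose = 300,
                      illustrative = FALSE) {
  two_cpt <- !is.null(q) || !is.null(vp)
  if (two_cpt) assert_that(!is.null(q) && !is.null(vp),
                           "two-compartment form needs both q and vp")
  vals <- c(ka = ka, cl = cl, v = v,
            if (two_cpt) c(q = q, vp = vp), dose = dose)
  assert_that(all(vals > 0), "all PK parameters must be positive")
  structure(list(ka = ka, cl = cl, v = v, q = q, vp = vp, dose = dose,
                 n_compartments = if (two_cpt) 2L else 1L,
                 illustrative = illustrative),
            class = "pk_params")
}

#' Illustrative tenofovir-like default PK parameters
#'
#' A clearly illustrative one-compartment parameter set with
#' tenofovir-plausible scale (terminal half-life about 14 h, average
#' concentration a few hundred ng/mL at daily 300 mg dosing). It is intended
#' for demonstrating the adherence-to-exposure cascade only; any quantitative
#' claim requires explicitly supplied, study-specific parameters.
#'
#' @return A `pk_params` object flagged `illustrative`.
#' @export
pk_defaults <- function() {
  pk_params(ka = 1.0, cl = 60, v = 1200, dose = 300, illustrative = TRUE)
}

#' Convert an adherence chain into a dosing history
#'
#' One dose at the configured clock time on each dose-taking day; nothing on
#' missed days. Day 1 of the chain is time 0 of the history.
#'
#' @param chain Integer 0/1 vector of daily states.
#' @param dose_time_of_day Clock time of intake (hours, default 8).
#' @param dose_mg Dose per administration (mg, default 300).
#' @return A tibble `time` (h from start of day 1), `amount` (mg), ordered.
#' @export
chain_to_doses <- function(chain, dose_time_of_day = 8, dose_mg = 300) {
  assert_that(length(chain) > 0, "chain is empty")
  assert_that(all(chain %in% c(0, 1)), "chain must be 0/1")
  taken <- which(chain == 1)
  tibble::tibble(time = (taken - 1) * 24 + dose_time_of_day,
                 amount = rep(dose_mg, length(taken)))
}

#' Simulate a plasma concentration profile by superposition
#'
#' Evaluates the closed-form single-dose solution of the chosen linear
#' compartment model for every dose and sums them on the time grid (legitimate
#' because the model is linear). Concentrations are returned in ng/mL
#' (dose mg / volume L x 1e3). The degenerate case `ka` equal to the
#' elimination rate constant is handled by its analytic limit.
#'
#' @param doses Tibble from [chain_to_doses()] (columns `time` in h, `amount`
#'   in mg).
#' @param params A [pk_params()] object.
#' @param times Strictly increasing time grid (h).
#' @return A tibble of class `concentration_profile` with columns `time`,
#'   `conc` (ng/mL).
#' @export
simulate_profile <- function(doses, params, times) {
  assert_that(inherits(params, "pk_params"), "params must be a pk_params object")
  assert_that(all(diff(times) > 0), "time grid must be strictly increasing")
  conc <- numeric(length(times))
  for (i in seq_len(nrow(doses))) {
    dt <- times - doses$time[i]
    conc <- conc + single_dose_conc(dt, doses$amount[i], params)
  }
  structure(tibble::tibble(time = times, conc = conc),
            class = c("concentration_profile", "tbl_df", "tbl", "data.frame"))
}

# Closed-form concentration (ng/mL) at time dt (h) after one oral dose.
single_dose_conc <- function(dt, amount, params) {
  out <- numeric(length(dt))
  pos <- dt > 0
  if (!any(pos)) return(out)
  t <- dt[pos]
  ka <- params$ka
  if (params$n_compartments == 1L) {
    ke <- params$cl / params$v
    if (abs(ka - ke) < 1e-8 * ka) {
      c_mg_l <- amount * ka * t * exp(-ka * t) / params$v
    } else {
      c_mg_l <- amount * ka / (params$v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
    }
  } else {
    k <- params$cl / params$v
    k12 <- params$q / params$v
    k21 <- params$q / params$vp
    s <- k + k12 + k21
    disc <- sqrt(s^2 - 4 * k * k21)
    alpha <- (s + disc) / 2
    beta <- (s - disc) / 2
    # the profile is continuous in ka; nudge ka off an exact collision with a
    # disposition rate instead of a separate limit branch
    if (min(abs(ka - alpha), abs(ka - beta)) < 1e-8 * ka) ka <- ka * (1 + 1e-7)
    A <- (k21 - alpha) / ((ka - alpha) * (beta - alpha))
    B <- (k21 - beta) / ((ka - beta) * (alpha - beta))
    C <- (k21 - ka) / ((alpha - ka) * (beta - ka))
    c_mg_l <- amount * ka / params$v *
      (A * exp(-alpha * t) + B * exp(-beta * t) + C * exp(-ka * t))
  }
  out[pos] <- c_mg_l * 1000
  out
}

#' Time-below-threshold metrics of a concentration profile
#'
#' Piecewise-linear interval accounting on the grid: time is counted as below
#' the threshold only where the interpolated concentration is strictly below
#' it, with exact crossing times found by linear interpolation within each
#' grid interval.
#'
#' @param profile A `concentration_profile` (or tibble with `time`, `conc`).
#' @param threshold Protection threshold (ng/mL; default 40, a plasma
#'   tenofovir protective benchmark).
#' @return A tibble with `fraction_below` (of total grid span),
#'   `longest_below` (h), `first_crossing` (h; first downward crossing, NA if
#'   never below).
#' @export
threshold_metrics <- function(profile, threshold = 40) {
  assert_that(nrow(profile) > 1, "profile needs at least two grid points")
  t <- profile$time; c0 <- profile$conc - threshold
  below_time <- 0; longest <- 0; current <- 0; first_cross <- NA_real_
  if (c0[1] < 0) first_cross <- t[1]
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    a <- c0[i]; b <- c0[i + 1]
    if (a < 0 && b < 0) {                      # stays below
      current <- current + dt
      below_time <- below_time + dt
    } else if (a >= 0 && b < 0) {              # downward crossing
      frac <- a / (a - b)
      if (is.na(first_cross)) first_cross <- t[i] + frac * dt
      current <- (1 - frac) * dt
      below_time <- below_time + current
    } else if (a < 0 && b >= 0) {              # upward crossing
      frac <- a / (a - b)
      current <- current + frac * dt
      below_time <- below_time + frac * dt
      longest <- max(longest, current)
      current <- 0
    } else {                                   # stays at or above
      longest <- max(longest, current)
      current <- 0
    }
  }
  longest <- max(longest, current)
  tibble::tibble(fraction_below = below_time / (t[length(t)] - t[1]),
                 longest_below = longest,
                 first_crossing = first_cross)
}

#' Comparative concentration profiles for a covariate's categories
#'
#' Illustrates the covariate-to-adherence-to-exposure cascade: for each
#' category of a covariate (indicator 0/1), builds the typical-subject
#' (random effects zero) transition matrix at the fitted or supplied
#' parameters, simulates an adherence chain, converts it to a dosing history
#' and computes the concentration profile.
#'
#' @param params A [markov_params()] object or a `markov_fit` (its estimates
#'   are used).
#' @param covariate Covariate name present in `beta01` and/or `beta10`.
#' @param pk A [pk_params()] object. If the set is flagged illustrative and
#'   `strict = TRUE`, the function refuses to run.
#' @param n_days Chain length in days (default 30).
#' @param other_covariates Named values for the remaining covariates
#'   (default: all at reference 0).
#' @param seed Optional integer seed (the two categories use independently
#'   drawn chains).
#' @param grid_step Profile grid step (h, default 0.5).
#' @param strict Refuse illustrative default PK parameters (default FALSE).
#' @return A list of class `covariate_profile_panel`: `profiles` tibble
#'   (`category`, `time`, `conc`), `doses` tibble (`category`, `time`,
#'   `amount`, `taken`), `matrices` tibble of the category transition
#'   probabilities, and `threshold` metrics per category.
#' @export
covariate_profile_panel <- function(params, covariate, pk = pk_defaults(),
                                    n_days = 30, other_covariates = NULL,
                                    seed = NULL, grid_step = 0.5,
                                    strict = FALSE) {
  if (inherits(params, "markov_fit")) params <- params$params
  assert_that(covariate %in% union(names(params$beta01), names(params$beta10)),
              paste0("covariate '", covariate, "' is not in the model"))
  if (strict && isTRUE(pk$illustrative)) {
    stop("illustrative default PK parameters refused under strict = TRUE; ",
         "supply study-specific pk_params()", call. = FALSE)
  }
  needed <- union(names(params$beta01), names(params$beta10))
  base <- stats::setNames(rep(0, length(needed)), needed)
  if (!is.null(other_covariates)) base[names(other_covariates)] <- other_covariates
  times <- seq(0, n_days * 24, by = grid_step)
  with_seed_maybe(seed, {
    out <- purrr::map(c(0, 1), function(val) {
      x <- base; x[covariate] <- val
      tp <- transition_probabilities(params, x, eta = c(0, 0))
      chain <- simulate_chain(tp["p01"], tp["p10"], n_days)
      doses <- chain_to_doses(chain, dose_mg = pk$dose)
      prof <- simulate_profile(doses, pk, times)
      list(tp = tp, chain = chain, doses = doses, prof = prof)
    })
    cat_names <- paste0(covariate, " = ", c(0, 1))
    profiles <- purrr::map2_dfr(out, cat_names, function(o, nm) {
      dplyr::mutate(tibble::as_tibble(o$prof), category = nm, .before = 1)
    })
    doses <- purrr::map2_dfr(out, cat_names, function(o, nm) {
      all_days <- tibble::tibble(
        category = nm,
        time = (seq_len(n_days) - 1) * 24 + 8,
        amount = pk$dose,
        taken = o$chain == 1
      )
      all_days
    })
    matrices <- purrr::map2_dfr(out, cat_names, function(o, nm) {
      tibble::tibble(category = nm, p01 = o$tp["p01"], p10 = o$tp["p10"],
                     p00 = o$tp["p00"], p11 = o$tp["p11"])
    })
    thr <- purrr::map2_dfr(out, cat_names, function(o, nm) {
      dplyr::mutate(threshold_metrics(o$prof), category = nm, .before = 1)
    })
    structure(list(profiles = profiles, doses = doses, matrices = matrices,
                   threshold = thr, covariate = covariate,
                   pk = pk),
              class = "covariate_profile_panel")
  })
}
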