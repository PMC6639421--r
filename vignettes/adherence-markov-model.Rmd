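---
title: "Modelling daily PrEP adherence as a mixed-effects Markov chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling daily PrEP adherence as a mixed-effects Markov chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(prepmarkov)
library(dplyr)
```

## The problem and the model

Electronic monitoring (MEMS) caps record a timestamp each time a medication
container is opened, giving a day-by-day binary record of dose-taking for every
subject in a cohort — here, HIV-uninfected members of serodiscordant couples
taking daily oral PrEP. Summary adherence percentages discard the *pattern* of
adherence: two subjects at 80% adherence may differ enormously in how their
missed doses cluster, and clustering is what determines time without drug
protection. Day-to-day dosing is also strongly autocorrelated; treating days as
independent coin flips both misstates the information content of the data and
inflates type-I error in covariate selection.

`prepmarkov` therefore models each subject's daily states $s_{id} \in \{0, 1\}$
("dose missing" / "dose taken") as a two-state, first-order, discrete-time
Markov chain. Writing $P_{01}$ for the re-initiation probability
($0 \to 1$) and $P_{10}$ for the discontinuation probability ($1 \to 0$), the
model places each on a logit scale:

$$\operatorname{logit} P_{01,id} = \theta_1 + x_{id}'\beta_{01} + \eta_{1i},
\qquad
\operatorname{logit} P_{10,id} = \theta_2 + x_{id}'\beta_{10} + \eta_{2i},$$

with $P_{00} = 1 - P_{01}$ and $P_{11} = 1 - P_{10}$. Covariates $x_{id}$ are
0/1 indicators (possibly time-varying, e.g. "beyond six months of follow-up"),
so each $\exp(\beta)$ is an odds ratio on a transition probability: an OR
below 1 on $P_{10}$ means lower odds of discontinuing (better persistence); an
OR above 1 on $P_{01}$ means higher odds of restarting after a miss. The
subject random effects $\eta_{1i}, \eta_{2i} \sim N(0, \omega^2_{1,2})$ absorb
unexplained between-subject heterogeneity. The comparator "coin-flip" model
(`fit_bernoulli()`) has a single dose-taking probability per subject,
$\operatorname{logit} P_{1,i} = \theta_1 + \eta_i$, and ignores the previous
day entirely.

Each subject's first day has no observed predecessor; its previous state is
set to 1 by default (`initial_state` in `build_transitions()`), appropriate
for cohorts that start dosing at enrolment with high initial adherence; the
choice is exposed because analyses of sparse starters may prefer 0.

## Estimation

Conditional on $(\eta_{1i}, \eta_{2i})$, a subject's likelihood is the product
of the daily transition probabilities. Because days with previous state 0
inform only the $P_{01}$ logit and days with previous state 1 only the
$P_{10}$ logit, the conditional likelihood factorises into two binomial
logistic blocks, and with independent random effects (the default) the
marginal likelihood factorises the same way. Each block's one-dimensional
integral over $\eta$ is approximated by the Laplace method: a damped,
vectorised Newton iteration finds every subject's posterior mode
simultaneously, and mode plus curvature give the approximate marginal
likelihood. Adaptive Gauss–Hermite quadrature with any node count
(`method = "agq"`) serves as the high-accuracy cross-check; on small data sets
the two agree to well under half a percent, and a 64-node quadrature is the
oracle the test suite holds the Laplace path against. A `random = "shared"`
option places one $\eta_i$ on both logits (the printed model equations are
ambiguous between the two structures; separate effects nest the shared case
approximately and are the default), and `random = "none"` gives the
fixed-effects model, whose maximum likelihood estimate is the empirical
transition-frequency table — a closed-form identity the tests exploit.

The outer optimisation is BFGS on $(\theta, \beta, \log\omega^2)$, started at
empirical logits of the pooled transition frequencies, zero coefficients and
$\omega^2 = 0.1$. Standard errors come from a central finite-difference
Hessian (step $10^{-4}$ on the working scale) of the negative marginal
log-likelihood; 95% intervals use the conventional 1.96 multiplier. All
likelihood arithmetic is on the log scale; probabilities are clipped to
$[10^{-12}, 1 - 10^{-12}]$ only inside logarithms. Refitting from a previous
optimum reproduces the objective to optimiser tolerance.

A worked example on a small synthetic cohort:

```{r fit-example}
spec <- cohort_spec(n_subjects = 150, n_days = 120, followup_switch_day = 61)
cohort <- generate_cohort(spec, seed = 7)

states <- daily_states(cohort$events, cohort$windows)
daily <- resolve_covariates(states,
                            cohort$covariates |> select(-sexrisk),
                            cohort$covariate_intervals)
transitions <- build_transitions(daily)

fit <- fit_markov(transitions,
                  p01 = names(spec$params$beta01),
                  p10 = names(spec$params$beta10))
glance(fit)
odds_ratios(fit)
```

## Covariate screening and model selection

Model building follows a full-model-then-prune strategy. `screen_covariates()`
first drops covariates too sparse to estimate: a covariate is excluded when,
within any one of its categories, any of the four transition types `[01]`,
`[11]`, `[10]`, `[00]` contributes strictly less than 5% of that category's
transitions (exactly 5% is retained; the rule can also be applied to pooled
transitions via `within = "pooled"`). `full_model_spec()` then places every
retained covariate on both logits, and `backward_eliminate()` iterates: fit,
compute Wald odds-ratio intervals, drop every covariate–parameter effect whose
interval contains 1, refit, until nothing drops. Elimination is per effect,
not per covariate — a covariate may survive on one logit only — and all
failing effects drop simultaneously by default (`drop = "one"` gives the
one-at-a-time variant; both are exposed because printed descriptions of such
procedures rarely pin this down). The returned history records every
iteration's estimates and drop decisions, and rerunning on the same data
reproduces it exactly.

## Diagnostics: non-therapeutic time and replicate transition counts

Non-therapeutic time (NTT) summarises *clustered* non-adherence: assuming each
dose protects for 24 h, a run of $k \ge 2$ consecutive missed days leaves
$k - 1$ unprotected days (the first miss is still covered by the previous
dose). `observed_ntt()` implements this rule; the alternative whole-run
accounting (a run of $k \ge 2$ zeros counts all $k$ days) is available as
`rule = "run"` because verbal definitions of NTT differ by exactly this one
day per run, and the 24-hour duration-of-action argument favours $k - 1$.

`ntt_diagnostic()` compares each subject's observed NTT with the mean NTT of
100 chains simulated from that subject's empirical-Bayes transition matrix
(posterior-mode random effects at the subject's modal covariate vector); the
across-subject correlation is the headline diagnostic, and the Markov model
should correlate far better than the coin-flip comparator on persistent data.
`replicate_transition_counts()` re-simulates every subject's full series
(same follow-up length, same per-day covariates, daily-recomputed
probabilities for time-varying covariates) and tallies the four transition
types per replicate; a coin-flip model characteristically overpredicts the
`[10]` and `[01]` switch counts, which is the signature that motivates the
Markov base model.

```{r diagnostics}
ntt <- ntt_diagnostic(fit, states, reps = 50, seed = 11)
ntt
replicate_transition_counts(fit, transitions, n_reps = 3, seed = 12)
```

## The synthetic-cohort generator

`cohort_spec()` defines the study conditions the package is tested under: 920
subjects followed 360 days, covariate prevalences matching the published
demographic mix (male 65%, age ≥ 25 80%, sex-risk classes 4/34/62%, partner on
ART ≥ 6 months 52%, wants-relationship 88%, problem alcohol 20%), covariate
effects at the published odds ratios, and $\omega^2 = 0.5$ per logit. Two
calibrations were fixed once, before any testing, and documented here as the
package's own choices: the intercepts $\theta_1 = -1.11$, $\theta_2 = -1.35$
put the cohort-average profile at $P_{01} \approx 0.28$,
$P_{10} \approx 0.11$, matching the reported dominance of `[11]` transitions
(about 65%, with roughly 7.5% each of `[01]`/`[10]`) and a stationary
adherence near 75%; and the follow-up > 6 months covariate is generated as a
deterministic within-subject switch at study day 183 rather than a
subject-level draw, because in a fully-followed synthetic cohort every subject
crosses the six-month mark (the published 57% prevalence reflects real-world
censoring, which the generator deliberately does not model).

Covariates are drawn independently (only marginal prevalences are published);
`inject_timevarying()` can convert any indicator into a per-subject switch,
re-simulating the chains with the same random effects. Each dose-taking day
emits exactly one opening timestamp, jittered uniformly over 06:00–22:00 to
exercise the timestamp parser. What the generator does *not* emulate — and
what passing tests therefore do not establish about real data — includes
curiosity/pocket openings (false positives), device loss and download gaps,
correlated covariates, couple-level structure, and behavioural drift within
subjects beyond the configured switches.

## The adherence-to-exposure cascade

`chain_to_doses()` turns a simulated or observed chain into a dosing history
(one dose per taken day at a fixed clock time), and `simulate_profile()`
evaluates a linear one- or two-compartment first-order-absorption model by
superposition of closed-form single-dose solutions — legitimate because the
model is linear, and verified in the tests against numerical ODE integration
to a relative error below $10^{-6}$. The absorption-equals-elimination
degenerate case uses the analytic limit. `threshold_metrics()` computes time
strictly below a protection threshold (default 40 ng/mL) by piecewise-linear
interval accounting, and `covariate_profile_panel()` contrasts the typical
subject (random effects zero) in each category of one covariate all the way
from transition matrix to concentration curve.

The bundled `pk_defaults()` parameter set (one compartment, $k_a = 1\,h^{-1}$,
CL/F = 60 L/h, V/F = 1200 L, 300 mg daily) is deliberately flagged
`illustrative`: it has tenofovir-plausible scale (about 14 h half-life,
troughs comfortably above 40 ng/mL under perfect adherence, dips below it
after two or more consecutive misses), but it is not a published population
model, and `strict = TRUE` refuses it so that quantitative work must supply
study-specific parameters.

```{r pk}
pars <- markov_params(qlogis(0.3), qlogis(0.12),
                      beta01 = c(alcohol = log(0.63)),
                      beta10 = c(alcohol = log(1.16)))
panel <- covariate_profile_panel(pars, "alcohol", n_days = 30, seed = 21)
panel$threshold
```

## Numerical choices and problem sizes

Tolerances and sizes used throughout were chosen as a balance between
statistical resolution and the few minutes a routine check should take, and
are stated here as the package's own defaults. The inner Newton iteration
stops when the largest step falls below $10^{-10}$ (steps capped at 4 on the
logit scale for robustness); BFGS runs with a relative tolerance of
$10^{-12}$. Unit tests exercise cohorts up to a few hundred subjects; the
acceptance experiment and the interval-calibration check run at the full
study scale of 920 subjects by 360 days, the latter pooled over ten seeded
replicates. The acceptance script averages recovered odds ratios over five
independently seeded cohorts to damp simulation noise in a stochastic
quantity; a single cohort's estimates are themselves unbiased, and its 95%
intervals cover the generating values.

## Known limitations

The chain is strictly first-order: longer-memory behaviour (weekend patterns,
drug holidays with structured restarts) is only captured insofar as it
projects onto the two transition probabilities. Random effects are Gaussian
on the logit scale with no covariate effects on their variance and no
inter-occasion variability. The Laplace approximation can bias variance
components at very short follow-up (few transitions per subject per logit);
the quadrature path is the guard. Backward elimination on confidence
intervals inherits the usual caveats of stepwise selection — the final
intervals are conditional on selection. The PK layer models plasma
concentration only; intracellular active-metabolite kinetics, which govern
efficacy more directly, are out of scope.
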