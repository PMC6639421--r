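# Internal numerical helpers shared across the likelihood and simulation code.

# log(1 + exp(x)) without overflow for large x or loss of precision for small x
log1pexp <- function(x) {
  out <- x
  small <- x <= 33
  out[small] <- log1p(exp(x[small]))
  out
}

expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

# probabilities are clipped only where they enter a log
clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Run code under a temporary seed when one is supplied, otherwise use the
# current RNG stream. Keeps every simulation reproducible from (inputs, seed).
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
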