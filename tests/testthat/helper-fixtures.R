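# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# a small synthetic trial + its max-scaled form, reused by several files
fixture_trial <- function() {
  if (is.null(fixture_env$trial)) {
    fixture_env$trial <- generate_trial(
      generator_config(seed = 401, n_timepoints = 12, noise_sd = 0.03))
  }
  fixture_env$trial
}

fixture_scaled <- function() {
  if (is.null(fixture_env$scaled))
    fixture_env$scaled <- max_scale(fixture_trial())
  fixture_env$scaled
}

# one moderately sampled MI(0) fit on the fixture trial (used by the
# feature-space and posterior-prediction tests; not held to formal
# convergence)
fixture_fit <- function() {
  if (is.null(fixture_env$fit)) {
    fixture_env$fit <- fit_variant(
      "MI(0)", fixture_scaled(),
      sampler = sampler_config(chains = 4, iter = 12000, warmup = 4000,
                               thin = 8, temps = 1, seed = 77,
                               rerun_on_ess_failure = FALSE))
  }
  fixture_env$fit
}

# deterministic draws-from-known-distribution helper for diagnostics tests
iid_chain_matrix <- function(n, m, seed = 1, shift = 0) {
  set.seed(seed)
  matrix(rnorm(n * m), n, m) + rep(shift * (seq_len(m) - 1), each = n)
}

# Conjugate Normal-mean model used as an exact-LOO oracle: y_i ~ N(mu, 1),
# mu ~ N(0, tau^2). Posterior and all leave-one-out predictive densities
# have closed forms, so exact LOO by n refits is available.
conjugate_case <- function(n = 8, tau = 10, S = 2000, seed = 14) {
  set.seed(seed)
  y <- rnorm(n, 1, 1)
  post_var <- 1 / (n + 1 / tau^2)
  post_mean <- post_var * sum(y)
  draws <- rnorm(S, post_mean, sqrt(post_var))
  log_lik <- vapply(seq_len(n),
                    function(i) dnorm(y[i], draws, 1, log = TRUE),
                    numeric(S))
  exact <- vapply(seq_len(n), function(i) {
    v <- 1 / (n - 1 + 1 / tau^2)
    m <- v * sum(y[-i])
    dnorm(y[i], m, sqrt(1 + v), log = TRUE)
  }, numeric(1))
  list(y = y, log_lik = log_lik, exact_elpd = sum(exact))
}

expect_rel_error_lt <- function(actual, expected, tol) {
  rel <- abs(actual - expected) / pmax(abs(expected), 1e-12)
  expect_lt(max(rel), tol)
}
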