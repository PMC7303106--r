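# closed-form conjugate posterior for Bayesian linear regression with known
# residual SD and independent zero-mean normal priors on (intercept, weights)
conjugate_posterior <- function(X, y, sigma, prior_sd) {
  X1 <- cbind(1, X)
  prec0 <- diag(1 / prior_sd^2, ncol(X1))
  V <- solve(crossprod(X1) / sigma^2 + prec0)
  list(mean = drop(V %*% crossprod(X1, y)) / sigma^2, cov = V)
}

# small deterministic cohort used by several preprocessing tests
tiny_cohort <- function(seed = 7, n_subjects = 3, n_days = 40, n_visits = 4,
                        ...) {
  generate_cohort(sim_config(n_subjects = n_subjects, n_days = n_days,
                             n_visits = n_visits, missing_rate = 0,
                             item_missing_rate = 0, visit_attend_prob = 1,
                             visit_jitter = 0, seed = seed, ...))
}

# quick sampler settings for unit tests
fast_sampler <- function(seed = 1, chains = 2, warmup = 300, draws = 600) {
  sampler_spec(chains = chains, warmup = warmup, draws = draws, seed = seed)
}
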