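make_lin_dataset <- function(J = 1, n = 40, P = 2, sigma = 1.5, seed = 1,
                             beta = NULL, alpha = NULL) {
  set.seed(seed)
  X <- matrix(runif(J * n * P, -1, 1), J * n, P,
              dimnames = list(NULL, paste0("f", seq_len(P))))
  sid <- rep(sprintf("S%02d", seq_len(J)), each = n)
  if (is.null(beta)) beta <- matrix(rnorm(J * P, 0, 2), J, P)
  if (is.null(alpha)) alpha <- rnorm(J, 5, 2)
  y <- alpha[match(sid, unique(sid))] +
    rowSums(X * beta[match(sid, unique(sid)), , drop = FALSE]) +
    rnorm(J * n, 0, sigma)
  list(ds = model_dataset(X, y, sid), X = X, y = y, sid = sid,
       alpha = alpha, beta = beta, sigma = sigma)
}

test_that("pooled fit with known sigma matches the conjugate closed form", {
  d <- make_lin_dataset(J = 1, n = 60, P = 2, sigma = 1.5, seed = 2)
  pr <- prior_spec(intercept_scale = 10, weight_scale = 5, sigma_fixed = 1.5)
  post <- fit_pooled_bayesian(d$ds, pr, fast_sampler(seed = 3, draws = 1500))
  oracle <- conjugate_posterior(d$X, d$y, 1.5, c(10, 5, 5))
  est <- colMeans(post$mu)
  sds <- apply(post$mu, 2, sd)
  ess <- pmax(coda::effectiveSize(coda::mcmc(post$mu)), 50)
  expect_true(all(abs(est - oracle$mean) < 4 * sds / sqrt(ess) + 0.02))
  expect_equal(unname(sds), unname(sqrt(diag(oracle$cov))), tolerance = 0.1)
})

test_that("hierarchical fit collapses to the conjugate form as tau -> 0", {
  d <- make_lin_dataset(J = 1, n = 60, P = 2, sigma = 1.5, seed = 4)
  pr <- prior_spec(intercept_scale = 10, weight_scale = 5, tau_scale = 0.01,
                   sigma_fixed = 1.5)
  post <- suppressWarnings(
    fit_hierarchical(d$ds, pr, fast_sampler(seed = 5, draws = 1500)))
  oracle <- conjugate_posterior(d$X, d$y, 1.5, c(10, 5, 5))
  expect_equal(unname(colMeans(post$mu)), unname(oracle$mean),
               tolerance = 0.08)
})

test_that("a zero target with zero-centred priors gives a zero intercept", {
  set.seed(6)
  X <- matrix(runif(80, -1, 1), 40, 2, dimnames = list(NULL, c("f1", "f2")))
  ds <- model_dataset(X, rep(0, 40), rep("a", 40))
  post <- suppressWarnings(
    fit_hierarchical(ds, prior_spec(), fast_sampler(seed = 7)))
  expect_lt(abs(mean(post$mu[, "intercept"])),
            4 * sd(post$mu[, "intercept"]) + 0.05)
})

test_that("pooled intercept-only fit concentrates at the constant target", {
  ds <- model_dataset(matrix(numeric(0), 30, 0), rep(4, 30), rep("a", 30))
  post <- fit_pooled_bayesian(ds, prior_spec(),
                              fast_sampler(seed = 8))
  expect_equal(mean(post$mu[, "intercept"]), 4, tolerance = 0.1)
  expect_lt(mean(post$sigma), 1)
})

test_that("fits are exactly reproducible given the sampler seed", {
  d <- make_lin_dataset(J = 3, n = 15, P = 2, seed = 9)
  p1 <- suppressWarnings(fit_hierarchical(d$ds, prior_spec(),
                                          fast_sampler(seed = 11)))
  p2 <- suppressWarnings(fit_hierarchical(d$ds, prior_spec(),
                                          fast_sampler(seed = 11)))
  expect_identical(p1$mu, p2$mu)
  expect_identical(p1$beta, p2$beta)
})

test_that("constant features are rejected with their name", {
  X <- cbind(f1 = runif(20), flat = rep(1, 20))
  ds <- model_dataset(X, rnorm(20), rep("a", 20))
  expect_error(suppressWarnings(fit_hierarchical(ds, prior_spec(),
                                                 fast_sampler())),
               "singular design.*flat")
  expect_error(fit_hierarchical(model_dataset(X[0, ], numeric(0),
                                              character(0))),
               "empty")
})

test_that("small tau-prior hierarchical and pooled fits agree", {
  d <- make_lin_dataset(J = 4, n = 20, P = 2, seed = 13)
  pr_h <- prior_spec(tau_scale = 0.005)
  h <- suppressWarnings(fit_hierarchical(d$ds, pr_h,
                                         fast_sampler(seed = 14, draws = 1200)))
  p <- fit_pooled_bayesian(d$ds, prior_spec(),
                           fast_sampler(seed = 15, draws = 1200))
  expect_lt(max(abs(colMeans(h$mu) - colMeans(p$mu))), 0.15)
})

test_that("subject posteriors sit between separate and pooled estimates", {
  d <- make_lin_dataset(J = 6, n = 25, P = 2, sigma = 1, seed = 16)
  post <- suppressWarnings(fit_hierarchical(d$ds, prior_spec(),
                                            fast_sampler(seed = 17)))
  pooled_fit <- lm(d$y ~ d$X)
  for (j in seq_along(unique(d$sid))) {
    s <- unique(d$sid)[j]
    idx <- d$sid == s
    sep_fit <- lm(d$y[idx] ~ d$X[idx, ])
    for (p in 1:2) {
      sep <- coef(sep_fit)[p + 1]
      pool <- coef(pooled_fit)[p + 1]
      est <- mean(post$beta[, j, p])
      lo <- min(sep, pool) - 0.35
      hi <- max(sep, pool) + 0.35
      expect_gte(est, lo)
      expect_lte(est, hi)
    }
  }
})

test_that("posterior predictive draws agree with the analytic mean", {
  d <- make_lin_dataset(J = 2, n = 30, P = 2, seed = 18)
  post <- suppressWarnings(fit_hierarchical(d$ds, prior_spec(),
                                            fast_sampler(seed = 19)))
  Xnew <- matrix(c(0.5, -0.5, 0.2, 0.8), 2, 2,
                 dimnames = list(NULL, c("f1", "f2")))
  sid <- c("S01", "S02")
  dr <- posterior_predict(post, Xnew, sid, include_noise = TRUE, seed = 20)
  pp <- point_predict(post, Xnew, sid)
  mc_se <- apply(dr, 2, sd) / sqrt(nrow(dr))
  expect_true(all(abs(colMeans(dr) - pp) < 4 * mc_se))
  # noiseless draws have strictly smaller spread
  dr0 <- posterior_predict(post, Xnew, sid, include_noise = FALSE)
  expect_true(all(apply(dr0, 2, sd) < apply(dr, 2, sd)))
  # point predictions are deterministic
  expect_identical(pp, point_predict(post, Xnew, sid))
  expect_error(posterior_predict(post, Xnew[, 2:1], sid),
               "feature-order mismatch")
})

test_that("unseen subjects fall back to the population distribution", {
  d <- make_lin_dataset(J = 4, n = 20, P = 2, seed = 21)
  pr <- prior_spec(tau_scale = 0.005)
  post <- suppressWarnings(fit_hierarchical(d$ds, pr,
                                            fast_sampler(seed = 22)))
  Xnew <- matrix(c(0.3, -0.7), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  # with tau ~ 0 a cold-start subject is predicted at the population mean
  pp_new <- point_predict(post, Xnew, "UNSEEN")
  mu <- colMeans(post$mu)
  expect_equal(pp_new, unname(mu[1] + Xnew %*% mu[-1])[1], tolerance = 1e-9)
  set.seed(23)
  dr_new <- posterior_predict(post, Xnew, "UNSEEN", include_noise = FALSE)
  dr_seen <- posterior_predict(post, Xnew, "S01", include_noise = FALSE)
  expect_equal(mean(dr_new), mean(dr_seen), tolerance = 0.1)
})

test_that("convergence diagnostics behave on iid, shifted and flat chains", {
  set.seed(24)
  iid <- coda::mcmc.list(coda::mcmc(cbind(theta = rnorm(2000))),
                         coda::mcmc(cbind(theta = rnorm(2000))))
  rep_iid <- convergence_report(iid)
  expect_lt(abs(rep_iid$rhat - 1), 0.01)
  expect_equal(rep_iid$flag, "")
  shifted <- coda::mcmc.list(coda::mcmc(cbind(theta = rnorm(500))),
                             coda::mcmc(cbind(theta = rnorm(500) + 2)))
  expect_gt(convergence_report(shifted)$rhat, 1.1)
  flat <- coda::mcmc.list(coda::mcmc(cbind(theta = rep(1, 500))),
                          coda::mcmc(cbind(theta = rep(1, 500))))
  expect_equal(convergence_report(flat)$flag, "degenerate")
})
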