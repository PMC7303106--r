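#' Prior specification for the Bayesian regression models
#'
#' Weakly-informative defaults on the scale of the normalised features and
#' the clinical rating scales: normal priors centred at zero on the
#' population weight means (scale 10 on the intercept, 5 on the weights)
#' and half-normal priors on the between-subject SDs `tau` and the residual
#' SD `sigma` (scale 5). `sigma_fixed` fixes the residual SD to a known
#' value instead of placing a prior on it.
#'
#' @param intercept_scale,weight_scale prior SDs of the population means.
#' @param tau_scale half-normal scale of the between-subject weight SDs.
#' @param sigma_scale half-normal scale of the residual SD.
#' @param sigma_fixed optional known residual SD.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(intercept_scale = 10, weight_scale = 5,
                       tau_scale = 5, sigma_scale = 5, sigma_fixed = NULL) {
  stopifnot(intercept_scale > 0, weight_scale > 0, tau_scale > 0,
            sigma_scale > 0, is.null(sigma_fixed) || sigma_fixed > 0)
  structure(list(intercept_scale = intercept_scale,
                 weight_scale = weight_scale, tau_scale = tau_scale,
                 sigma_scale = sigma_scale, sigma_fixed = sigma_fixed),
            class = "prior_spec")
}

#' MCMC sampler settings
#'
#' @param chains number of chains (at least 2, for convergence diagnostics).
#' @param warmup adaptation/burn-in iterations per chain.
#' @param draws retained sampling iterations per chain.
#' @param seed integer seed; all chains derive their RNG state from it.
#' @param thin thinning interval.
#' @return object of class `sampler_spec`.
#' @export
sampler_spec <- function(chains = 4, warmup = 500, draws = 1000,
                         seed = 1L, thin = 1) {
  stopifnot(chains >= 2, warmup >= 100, draws >= 100, thin >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), seed = as.integer(seed),
                 thin = as.integer(thin)), class = "sampler_spec")
}

#' Minimal modelling dataset from a design matrix
#'
#' Programmatic constructor used when the design matrix and targets are
#' already in hand (fixtures, oracles); [assemble_dataset()] is the usual
#' entry point from raw cohort tables.
#'
#' @param X numeric design matrix with feature column names.
#' @param y numeric targets.
#' @param subject_id subject identifier per row.
#' @param target_name label for the target.
#' @return a `model_dataset`.
#' @export
model_dataset <- function(X, y, subject_id, target_name = "hdrs_total") {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(subject_id) == length(y))
  structure(list(
    data = data.frame(subject_id = as.character(subject_id),
                      date = rep(as.Date(NA), length(y)),
                      visit_date = rep(as.Date(NA), length(y)), y = y),
    X = X, target_name = target_name, feature_set = "custom",
    features = colnames(X),
    subjects = sort(unique(as.character(subject_id)))),
    class = "model_dataset")
}

# JAGS model source; the hierarchical variant uses a non-centered
# parameterization (b = mu + tau * z with z ~ N(0,1))
.jags_source <- function(hierarchical, P, sigma_fixed) {
  lik_mean <- if (P > 0)
    if (hierarchical) "b[subj[i],1] + inprod(b[subj[i],2:P1], X[i,])"
    else "b[1] + inprod(b[2:P1], X[i,])"
  else if (hierarchical) "b[subj[i],1]" else "b[1]"
  # half-normal scales via an absolute-value fold of an unbounded normal;
  # avoids truncation-boundary pathologies when the posterior piles up at 0
  # the 0.001 floor keeps the precision finite on degenerate (perfect-fit)
  # targets; it is far below any realistic rating-scale residual SD
  sigma_line <- if (sigma_fixed) "" else
    "  sigma_raw ~ dnorm(0, prec_sigma)\n  sigma <- max(abs(sigma_raw), 0.001)\n"
  if (hierarchical) paste0(
    "model {\n",
    "  mu[1] ~ dnorm(0, prec_int)\n",
    if (P > 0) "  for (p in 2:P1) { mu[p] ~ dnorm(0, prec_w) }\n" else "",
    "  for (p in 1:P1) { tau_raw[p] ~ dnorm(0, prec_tau)\n",
    "                    tau[p] <- abs(tau_raw[p]) }\n",
    sigma_line,
    "  for (j in 1:J) { for (p in 1:P1) {\n",
    "    z[j,p] ~ dnorm(0, 1)\n",
    "    b[j,p] <- mu[p] + tau[p] * z[j,p]\n",
    "  } }\n",
    "  for (i in 1:N) { y[i] ~ dnorm(", lik_mean, ", pow(sigma, -2)) }\n",
    "}\n")
  else paste0(
    "model {\n",
    "  b[1] ~ dnorm(0, prec_int)\n",
    if (P > 0) "  for (p in 2:P1) { b[p] ~ dnorm(0, prec_w) }\n" else "",
    sigma_line,
    "  for (i in 1:N) { y[i] ~ dnorm(", lik_mean, ", pow(sigma, -2)) }\n",
    "}\n")
}

.fit_bayes <- function(dataset, priors, sampler, hierarchical) {
  stopifnot(inherits(dataset, "model_dataset"),
            inherits(priors, "prior_spec"),
            inherits(sampler, "sampler_spec"))
  y <- dataset$data$y
  X <- dataset$X
  if (!nrow(dataset$data)) stop("empty dataset")
  P <- ncol(X)
  if (P > 0) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop("singular design: constant feature(s): ",
           paste(colnames(X)[sds == 0], collapse = ", "))
  }
  subjects <- dataset$subjects
  subj <- match(dataset$data$subject_id, subjects)
  J <- length(subjects)
  sigma_fixed <- !is.null(priors$sigma_fixed)

  data <- list(y = y, N = length(y),
               prec_int = priors$intercept_scale^-2)
  if (P > 0) {
    data$X <- X
    data$P1 <- P + 1L
    data$prec_w <- priors$weight_scale^-2
  }
  if (hierarchical) {
    data$subj <- subj
    data$J <- J
    data$prec_tau <- priors$tau_scale^-2
    if (P == 0) data$P1 <- 1L
  }
  if (sigma_fixed) data$sigma <- priors$sigma_fixed
  else data$prec_sigma <- priors$sigma_scale^-2

  inits <- lapply(seq_len(sampler$chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (sampler$seed %% 1000000L) * 1000L + ch)
    if (!sigma_fixed) ini$sigma_raw <- stats::sd(y) + 1
    if (hierarchical) {
      ini$mu <- rep(0, P + 1L)
      ini$tau_raw <- rep(0.5, P + 1L)
      ini$z <- matrix(0, J, P + 1L)
    } else ini$b <- rep(0, P + 1L)
    ini
  })
  monitors <- if (hierarchical) c("mu", "tau", "b") else "b"
  if (!sigma_fixed) monitors <- c(monitors, "sigma")

  m <- rjags::jags.model(textConnection(
    .jags_source(hierarchical, P, sigma_fixed)), data = data,
    inits = inits, n.chains = sampler$chains, n.adapt = sampler$warmup,
    quiet = TRUE)
  update(m, sampler$warmup, progress.bar = "none")
  mc <- rjags::coda.samples(m, monitors, n.iter = sampler$draws,
                            thin = sampler$thin, progress.bar = "none")

  dm <- do.call(rbind, lapply(mc, as.matrix))
  ndraw_chain <- nrow(as.matrix(mc[[1]]))
  chain <- rep(seq_len(sampler$chains), each = ndraw_chain)
  par_names <- c("intercept", colnames(X))
  P1 <- P + 1L

  get_cols <- function(prefix, idx) {
    nms <- paste0(prefix, "[", idx, "]")
    # coda drops the index on scalar nodes
    if (length(idx) == 1 && !nms %in% colnames(dm)) nms <- prefix
    dm[, nms, drop = FALSE]
  }
  if (hierarchical) {
    mu <- get_cols("mu", seq_len(P1))
    tau <- get_cols("tau", seq_len(P1))
    colnames(mu) <- colnames(tau) <- par_names
    bcols <- outer(seq_len(J), seq_len(P1),
                   function(j, p) paste0("b[", j, ",", p, "]"))
    b <- array(dm[, as.vector(bcols)], dim = c(nrow(dm), J, P1),
               dimnames = list(NULL, subjects, par_names))
    alpha <- b[, , 1, drop = TRUE]
    if (J == 1) alpha <- matrix(alpha, ncol = 1)
    colnames(alpha) <- subjects
    beta <- b[, , -1, drop = FALSE]
  } else {
    mu <- get_cols("b", seq_len(P1))
    colnames(mu) <- par_names
    tau <- NULL
    alpha <- matrix(mu[, 1], ncol = 1, dimnames = list(NULL, "(pooled)"))
    beta <- array(mu[, -1, drop = FALSE], dim = c(nrow(dm), 1, P),
                  dimnames = list(NULL, "(pooled)", colnames(X)))
  }
  sigma <- if (sigma_fixed) rep(priors$sigma_fixed, nrow(dm)) else
    dm[, "sigma"]

  post <- structure(list(
    mu = mu, tau = tau, sigma = sigma, alpha = alpha, beta = beta,
    chain = chain, mcmc = mc,
    model = if (hierarchical) "hierarchical" else "pooled",
    features = colnames(X), subjects = subjects,
    target_name = dataset$target_name, feature_set = dataset$feature_set,
    priors = priors, sampler = sampler), class = "posterior_samples")
  post$convergence <- convergence_report(post, warn = TRUE)
  post
}

#' Fit the hierarchical Bayesian regression
#'
#' Each subject j has its own intercept and weight vector
#' `(alpha_j, beta_j) ~ Normal(mu, tau)` drawn from a population
#' distribution with per-parameter means `mu` and SDs `tau`, and
#' observations `y_ji ~ Normal(alpha_j + beta_j' x_ji, sigma)`. Partial
#' pooling regularises data-poor subjects toward the population. Sampling
#' uses JAGS with a non-centered parameterization.
#'
#' @param dataset a `model_dataset`.
#' @param priors a [prior_spec()].
#' @param sampler a [sampler_spec()].
#' @return a `posterior_samples` object carrying draws of `mu`, `tau`,
#'   `sigma` and per-subject `alpha`/`beta`, with a convergence report.
#' @export
fit_hierarchical <- function(dataset, priors = prior_spec(),
                             sampler = sampler_spec()) {
  .fit_bayes(dataset, priors, sampler, hierarchical = TRUE)
}

#' Fit the pooled Bayesian regression baseline
#'
#' A single shared intercept and weight vector for the whole population
#' (complete pooling); the no-pooling limit of the hierarchy.
#'
#' @inheritParams fit_hierarchical
#' @return a `posterior_samples` object (no `tau`).
#' @export
fit_pooled_bayesian <- function(dataset, priors = prior_spec(),
                                sampler = sampler_spec()) {
  .fit_bayes(dataset, priors, sampler, hierarchical = FALSE)
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples>", x$model, "model for", x$target_name, "\n ",
      nrow(x$mu), "draws,", length(x$subjects), "subjects,",
      length(x$features), "features\n")
  bad <- x$convergence$flag != ""
  if (any(bad)) cat("  convergence flags on:",
                    paste(x$convergence$parameter[bad], collapse = ", "), "\n")
  invisible(x)
}

# linear-predictor draws for rows of (X, subject); unseen subjects get a
# fresh (alpha, beta) ~ Normal(mu, tau) per draw (hierarchical) or the
# shared parameters (pooled)
.linpred_draws <- function(post, X, subject_id) {
  if (!identical(colnames(X), post$features))
    stop("feature-order mismatch: expected ",
         paste(post$features, collapse = ", "))
  n <- nrow(X)
  D <- nrow(post$mu)
  out <- matrix(NA_real_, D, n)
  sid <- if (post$model == "pooled") rep("(pooled)", n) else
    as.character(subject_id)
  for (s in unique(sid)) {
    idx <- which(sid == s)
    j <- match(s, colnames(post$alpha))
    if (!is.na(j)) {
      a <- post$alpha[, j]
      B <- matrix(post$beta[, j, ], nrow = D)
    } else {
      P1 <- ncol(post$mu)
      z <- matrix(stats::rnorm(D * P1), D, P1)
      ab <- post$mu + post$tau * z
      a <- ab[, 1]
      B <- ab[, -1, drop = FALSE]
    }
    out[, idx] <- a + B %*% t(X[idx, , drop = FALSE])
  }
  out
}

#' Posterior predictive draws
#'
#' For each posterior draw, `ytilde = alpha_j + beta_j' x + Normal(0, sigma)`.
#' Subjects unseen at fit time receive a fresh `(alpha, beta) ~
#' Normal(mu, tau)` per draw (cold start via the population distribution).
#'
#' @param post a `posterior_samples` object.
#' @param X design matrix with columns in the fitted feature order.
#' @param subject_id subject per row of `X`.
#' @param include_noise add observation noise `Normal(0, sigma)` (the full
#'   posterior predictive); `FALSE` returns linear-predictor draws.
#' @param seed optional seed for the predictive RNG.
#' @return matrix of draws (rows) by observations (columns)... transposed
#'   convention: `n_draws` x `n_rows`.
#' @export
posterior_predict <- function(post, X, subject_id, include_noise = TRUE,
                              seed = NULL) {
  stopifnot(inherits(post, "posterior_samples"))
  if (!is.null(seed)) set.seed(seed)
  lin <- .linpred_draws(post, X, subject_id)
  if (include_noise)
    lin <- lin + matrix(stats::rnorm(length(lin), 0, post$sigma),
                        nrow(lin), ncol(lin))
  lin
}

#' Point predictions (posterior predictive mean)
#'
#' The mean of the posterior predictive distribution, which equals the
#' posterior mean of the linear predictor since the observation noise has
#' zero mean; deterministic given the draws. Unseen subjects receive the
#' population-mean prediction `E[mu]' (1, x)`.
#'
#' @inheritParams posterior_predict
#' @return numeric vector of predictions, one per row of `X`.
#' @export
point_predict <- function(post, X, subject_id) {
  stopifnot(inherits(post, "posterior_samples"))
  if (!identical(colnames(X), post$features))
    stop("feature-order mismatch: expected ",
         paste(post$features, collapse = ", "))
  n <- nrow(X)
  sid <- if (post$model == "pooled") rep("(pooled)", n) else
    as.character(subject_id)
  out <- numeric(n)
  mu_mean <- colMeans(post$mu)
  for (s in unique(sid)) {
    idx <- which(sid == s)
    j <- match(s, colnames(post$alpha))
    if (!is.na(j)) {
      a <- mean(post$alpha[, j])
      bb <- colMeans(matrix(post$beta[, j, ], nrow = nrow(post$mu)))
    } else {
      a <- mu_mean[1]
      bb <- mu_mean[-1]
    }
    out[idx] <- a + drop(X[idx, , drop = FALSE] %*% bb)
  }
  out
}

#' Convergence diagnostics
#'
#' Split-chain style diagnostics from the coda machinery: potential scale
#' reduction factor (R-hat) and effective sample size per monitored
#' population parameter. Parameters with R-hat above 1.05 or effective
#' sample size below 100 are flagged; chains with zero variance are flagged
#' as degenerate.
#'
#' @param post a `posterior_samples` object or a `coda::mcmc.list`.
#' @param warn emit a warning naming flagged parameters.
#' @return data.frame with columns `parameter`, `rhat`, `ess`, `flag`.
#' @export
convergence_report <- function(post, warn = FALSE) {
  mc <- if (inherits(post, "posterior_samples")) {
    keep <- grep("^(mu|tau|sigma|b)\\[|^sigma$",
                 coda::varnames(post$mcmc), value = TRUE)
    keep <- keep[!grepl("^b\\[", keep) | post$model == "pooled"]
    post$mcmc[, keep, drop = FALSE]
  } else post
  vn <- coda::varnames(mc)
  vars <- vapply(vn, function(v)
    stats::var(unlist(lapply(mc, function(ch) as.numeric(ch[, v])))),
    numeric(1))
  rhat <- rep(NA_real_, length(vn))
  ok <- vars > 1e-12
  if (any(ok)) {
    gd <- try(coda::gelman.diag(mc[, vn[ok], drop = FALSE],
                                autoburnin = FALSE,
                                multivariate = FALSE)$psrf[, 1],
              silent = TRUE)
    if (!inherits(gd, "try-error")) rhat[ok] <- gd
  }
  ess <- as.numeric(coda::effectiveSize(mc))[seq_along(vn)]
  flag <- ifelse(!ok, "degenerate",
                 ifelse(!is.na(rhat) & rhat > 1.05, "rhat",
                        ifelse(ess < 100, "low_ess", "")))
  rep <- data.frame(parameter = vn, rhat = rhat, ess = ess, flag = flag,
                    stringsAsFactors = FALSE)
  if (warn && any(rep$flag %in% c("rhat", "low_ess")))
    warning("possible non-convergence (R-hat > 1.05 or ESS < 100): ",
            paste(rep$parameter[rep$flag %in% c("rhat", "low_ess")],
                  collapse = ", "), call. = FALSE)
  rep
}
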