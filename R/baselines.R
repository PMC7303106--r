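#' Baseline comparison models
#'
#' The non-Bayesian comparison models: naive means, L2-regularised (ridge)
#' linear regression and gradient-boosted tree regression, each in a pooled
#' (one model for everyone) and a separate (one model per subject) variant.
#' All consume the same engineered feature matrix as the Bayesian models.
#'
#' @param kind one of `"pooled_mean"`, `"separate_mean"`, `"pooled_l2"`,
#'   `"separate_l2"`, `"pooled_gbt"`, `"separate_gbt"`.
#' @param lambda L2 penalty for the ridge variants (glmnet convention,
#'   default 1 on the normalised features).
#' @param nrounds,max_depth,learning_rate boosted-tree settings
#'   (defaults 100 rounds, depth 3, rate 0.1).
#' @param seed RNG seed for the tree learner.
#' @return object of class `baseline_model` (unfitted).
#' @export
baseline_model <- function(kind = c("pooled_mean", "separate_mean",
                                    "pooled_l2", "separate_l2",
                                    "pooled_gbt", "separate_gbt"),
                           lambda = 1, nrounds = 100, max_depth = 3,
                           learning_rate = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, lambda = lambda, nrounds = nrounds,
                 max_depth = max_depth, learning_rate = learning_rate,
                 seed = as.integer(seed), fitted = NULL),
            class = "baseline_model")
}

.fit_l2 <- function(X, y, lambda) {
  glmnet::glmnet(X, y, alpha = 0, lambda = lambda, standardize = FALSE,
                 thresh = 1e-12)
}

.fit_gbt <- function(X, y, model) {
  set.seed(model$seed)
  xgboost::xgboost(x = X, y = y, nrounds = model$nrounds,
                   max_depth = model$max_depth,
                   learning_rate = model$learning_rate,
                   nthreads = 1, verbosity = 0, seed = model$seed)
}

#' Fit a baseline model
#'
#' Mean models store training means (global or per subject); regression
#' variants fit on the engineered features. Separate regression models for
#' subjects with fewer training rows than `ncol(X) + 2` fall back to that
#' subject's mean (the per-subject fit would be ill-posed); subjects unseen
#' at fit time fall back to the pooled statistic at prediction.
#'
#' @param model a [baseline_model()].
#' @param dataset a `model_dataset`.
#' @return the fitted `baseline_model`.
#' @export
fit_baseline <- function(model, dataset) {
  stopifnot(inherits(model, "baseline_model"),
            inherits(dataset, "model_dataset"))
  y <- dataset$data$y
  if (!length(y)) stop("empty dataset")
  X <- dataset$X
  sid <- dataset$data$subject_id
  f <- list(features = colnames(X), pooled_mean = mean(y))
  if (model$kind == "separate_mean" || grepl("^separate", model$kind)) {
    n_by <- table(sid)
    if (any(n_by == 0)) stop("subject with zero training rows")
  }
  f <- switch(model$kind,
    pooled_mean = f,
    separate_mean = c(f, list(
      subject_means = tapply(y, sid, mean))),
    pooled_l2 = c(f, list(l2 = .fit_l2(X, y, model$lambda))),
    separate_l2 = c(f, list(
      subject_means = tapply(y, sid, mean),
      sub = lapply(split(seq_along(y), sid), function(idx)
        if (length(idx) >= ncol(X) + 2)
          .fit_l2(X[idx, , drop = FALSE], y[idx], model$lambda) else NULL))),
    pooled_gbt = c(f, list(gbt = .fit_gbt(X, y, model))),
    separate_gbt = c(f, list(
      subject_means = tapply(y, sid, mean),
      sub = lapply(split(seq_along(y), sid), function(idx)
        if (length(idx) >= 3)
          .fit_gbt(X[idx, , drop = FALSE], y[idx], model) else NULL))))
  model$fitted <- f
  model
}

#' Predict from a fitted baseline model
#'
#' @param object a fitted `baseline_model`.
#' @param X design matrix in the fitted feature order.
#' @param subject_id subject per row (used by separate variants; unseen
#'   subjects get the pooled fallback).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.baseline_model <- function(object, X, subject_id = NULL, ...) {
  f <- object$fitted
  if (is.null(f)) stop("model not fitted")
  if (!identical(colnames(X), f$features))
    stop("feature-order mismatch")
  n <- nrow(X)
  sid <- as.character(subject_id)
  switch(object$kind,
    pooled_mean = rep(f$pooled_mean, n),
    separate_mean = {
      m <- as.numeric(f$subject_means[sid])
      ifelse(is.na(m), f$pooled_mean, m)
    },
    pooled_l2 = drop(stats::predict(f$l2, newx = X)),
    pooled_gbt = stats::predict(f$gbt, X),
    separate_l2 = ,
    separate_gbt = {
      out <- numeric(n)
      for (s in unique(sid)) {
        idx <- which(sid == s)
        sub <- f$sub[[s]]
        out[idx] <- if (!s %in% names(f$subject_means)) f$pooled_mean
        else if (is.null(sub)) f$subject_means[[s]]
        else if (object$kind == "separate_l2")
          drop(stats::predict(sub, newx = X[idx, , drop = FALSE]))
        else stats::predict(sub, X[idx, , drop = FALSE])
      }
      out
    })
}

#' @export
print.baseline_model <- function(x, ...) {
  cat("<baseline_model>", x$kind,
      if (is.null(x$fitted)) "(unfitted)" else "(fitted)", "\n")
  invisible(x)
}
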