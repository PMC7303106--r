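#' Predicted coefficient of determination
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, with the mean taken
#' over the held-out targets themselves, so a model that always predicts
#' the held-out mean scores exactly 0 and worse models score negative.
#' Undefined (returned as `NA`) when the held-out targets have zero
#' variance.
#'
#' @param y_true,y_pred numeric vectors of equal nonzero length.
#' @return a real number `<= 1`, or `NA` if undefined.
#' @export
predicted_r2 <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Root mean square error
#'
#' @inheritParams predicted_r2
#' @return nonnegative real.
#' @export
rmse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  sqrt(mean((y_true - y_pred)^2))
}

#' Build a hold-one-clinical-evaluation-per-subject cross-validation plan
#'
#' In each of `K` iterations, one randomly chosen clinical evaluation per
#' subject — together with its whole validity window of up to 4 day-rows —
#' is held out, and the remaining rows form the training fold. Requires
#' every subject in the dataset to have at least 3 distinct evaluations so
#' that at least 2 remain for training.
#'
#' @param dataset a `model_dataset` from [assemble_dataset()].
#' @param K number of iterations.
#' @param seed RNG seed; the plan is deterministic given it.
#' @return object of class `cv_plan` with a `held_out` table
#'   (iteration, subject_id, visit_date).
#' @export
make_cv_plan <- function(dataset, K, seed = 1L) {
  stopifnot(inherits(dataset, "model_dataset"), K >= 1)
  visits <- tapply(dataset$data$visit_date, dataset$data$subject_id,
                   function(v) sort(unique(v)), simplify = FALSE)
  nv <- vapply(visits, length, integer(1))
  if (any(nv < 3))
    stop("ineligible subject(s) with fewer than 3 distinct evaluations: ",
         paste(names(nv)[nv < 3], collapse = ", "))
  set.seed(seed)
  held <- do.call(rbind, lapply(names(visits), function(s)
    data.frame(subject_id = s,
               visit_date = sample(visits[[s]], K, replace = TRUE),
               iteration = seq_len(K), stringsAsFactors = FALSE)))
  held <- held[order(held$iteration, held$subject_id),
               c("iteration", "subject_id", "visit_date")]
  rownames(held) <- NULL
  structure(list(held_out = held, K = as.integer(K), seed = as.integer(seed),
                 subjects = names(visits)), class = "cv_plan")
}

#' Bayesian model specification for cross-validation
#'
#' Lightweight spec pairing a model kind with priors and sampler settings,
#' consumed by [run_cv()].
#'
#' @param kind `"hierarchical"` or `"pooled_bayesian"`.
#' @param priors a [prior_spec()].
#' @param sampler a [sampler_spec()]; its seed is re-derived per iteration.
#' @return object of class `bayes_model`.
#' @export
bayes_model <- function(kind = c("hierarchical", "pooled_bayesian"),
                        priors = prior_spec(), sampler = sampler_spec()) {
  kind <- match.arg(kind)
  structure(list(kind = kind, priors = priors, sampler = sampler),
            class = "bayes_model")
}

#' Run the cross-validation experiment
#'
#' Fits every model on each training fold (fold-specific sleep means are
#' recomputed from training data only, so no information leaks from the
#' held-out rows) and scores the pooled held-out rows of each iteration
#' with predicted R2 and RMSE. Bayesian models also yield relapse-risk
#' scores `Pr(ytilde >= threshold)` from their posterior predictive draws;
#' mean/regression baselines yield the indicator `1{yhat >= threshold}`.
#' A model failure in one iteration is recorded without aborting the run.
#'
#' @param models named list of [baseline_model()] / [bayes_model()] objects.
#' @param dataset a `model_dataset` from [assemble_dataset()].
#' @param plan a [make_cv_plan()] plan for this dataset.
#' @param threshold relapse threshold for risk scores (default 13).
#' @param collect_risk also return per-row predictions and risk scores.
#' @return object of class `cv_result`: `table` of per-iteration metrics,
#'   optional `predictions`, and `failures`.
#' @export
run_cv <- function(models, dataset, plan, threshold = 13,
                   collect_risk = TRUE) {
  stopifnot(inherits(plan, "cv_plan"), !is.null(names(models)))
  if (!setequal(plan$subjects, dataset$subjects))
    stop("plan is not consistent with dataset subjects")
  dat <- dataset$data
  res <- list()
  preds <- list()
  fails <- list()
  for (k in seq_len(plan$K)) {
    hk <- plan$held_out[plan$held_out$iteration == k, ]
    test_idx <- which(paste(dat$subject_id, dat$visit_date) %in%
                        paste(hk$subject_id, hk$visit_date))
    train_idx <- setdiff(seq_len(nrow(dat)), test_idx)
    test_keys <- dat[test_idx, c("subject_id", "date")]
    Xtr <- .fold_features(dataset, train_idx, test_keys)
    Xte <- .fold_features(dataset, test_idx, test_keys)
    tr <- model_dataset(Xtr, dat$y[train_idx], dat$subject_id[train_idx],
                        dataset$target_name)
    seed_k <- plan$seed + 7919L * k
    for (mn in names(models)) {
      m <- models[[mn]]
      out <- tryCatch({
        if (inherits(m, "bayes_model")) {
          sp <- m$sampler
          sp$seed <- seed_k
          post <- suppressWarnings(if (m$kind == "hierarchical")
            fit_hierarchical(tr, m$priors, sp)
          else fit_pooled_bayesian(tr, m$priors, sp))
          yhat <- point_predict(post, Xte, dat$subject_id[test_idx])
          risk <- if (collect_risk) {
            dr <- posterior_predict(post, Xte, dat$subject_id[test_idx],
                                    include_noise = TRUE, seed = seed_k)
            exceedance_probability(dr, threshold)$probability
          } else NULL
        } else {
          m$seed <- seed_k
          fit <- fit_baseline(m, tr)
          yhat <- predict(fit, Xte, dat$subject_id[test_idx])
          risk <- if (collect_risk) as.numeric(yhat >= threshold) else NULL
        }
        list(yhat = yhat, risk = risk)
      }, error = function(e) e)
      if (inherits(out, "error")) {
        fails[[length(fails) + 1L]] <-
          data.frame(iteration = k, model = mn,
                     message = conditionMessage(out))
        next
      }
      y_te <- dat$y[test_idx]
      res[[length(res) + 1L]] <- data.frame(
        iteration = k, model = mn, target = dataset$target_name,
        feature_set = dataset$feature_set,
        r2 = predicted_r2(y_te, out$yhat), rmse = rmse(y_te, out$yhat))
      if (collect_risk)
        preds[[length(preds) + 1L]] <- data.frame(
          iteration = k, model = mn,
          subject_id = dat$subject_id[test_idx], date = dat$date[test_idx],
          y = y_te, yhat = out$yhat, risk = out$risk,
          stringsAsFactors = FALSE)
    }
  }
  structure(list(
    table = if (length(res)) do.call(rbind, res) else NULL,
    predictions = if (length(preds)) do.call(rbind, preds) else NULL,
    failures = if (length(fails)) do.call(rbind, fails) else NULL,
    threshold = threshold, K = plan$K, seed = plan$seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$K, "iterations\n")
  if (!is.null(x$table)) {
    agg <- stats::aggregate(cbind(r2, rmse) ~ model, x$table, mean,
                            na.action = stats::na.omit)
    print(agg, row.names = FALSE)
  }
  if (!is.null(x$failures))
    cat("  failures:", nrow(x$failures), "\n")
  invisible(x)
}

#' Compare two models over cross-validation iterations
#'
#' Two-sample t test (Welch, two-sided) on the per-iteration metric values
#' of two models.
#'
#' @param cv a `cv_result`.
#' @param model_a,model_b model names present in `cv$table`.
#' @param metric `"r2"` or `"rmse"`.
#' @return list with `statistic`, `p.value`, and per-model means.
#' @export
compare_models <- function(cv, model_a, model_b, metric = c("r2", "rmse")) {
  metric <- match.arg(metric)
  a <- cv$table[[metric]][cv$table$model == model_a]
  b <- cv$table[[metric]][cv$table$model == model_b]
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 iterations per model")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    d <- mean(a) - mean(b)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                p.value = if (d == 0) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       mean_a = mean(a), mean_b = mean(b))
}

#' Absolute t-statistic of a posterior mean
#'
#' Variable importance of a population weight: the posterior mean scaled by
#' its standard error (the posterior SD), in absolute value.
#'
#' @param mean,sd posterior mean and SD of the parameter.
#' @return `abs(mean) / sd`.
#' @export
importance_t <- function(mean, sd) abs(mean) / sd

#' Posterior variable-importance table
#'
#' Per population weight: posterior mean, SD, central 95% credible interval
#' and the absolute t-statistic `|t| = |mean|/SD`, sorted by `|t|`
#' descending. For hierarchical fits the between-subject SD `tau` is
#' summarised alongside (it reads as the amount of pooling per variable).
#'
#' @param post a `posterior_samples` object.
#' @return data.frame sorted by `abs_t` descending.
#' @export
variable_importance <- function(post) {
  stopifnot(inherits(post, "posterior_samples"))
  q <- function(m, p) apply(m, 2, stats::quantile, probs = p)
  out <- data.frame(
    predictor = colnames(post$mu),
    mean = colMeans(post$mu), sd = apply(post$mu, 2, stats::sd),
    ci_low = q(post$mu, 0.025), ci_high = q(post$mu, 0.975),
    stringsAsFactors = FALSE)
  out$abs_t <- importance_t(out$mean, out$sd)
  if (!is.null(post$tau)) {
    out$tau_mean <- colMeans(post$tau)
    out$tau_sd <- apply(post$tau, 2, stats::sd)
    out$tau_ci_low <- q(post$tau, 0.025)
    out$tau_ci_high <- q(post$tau, 0.975)
  }
  out <- out[order(-out$abs_t), ]
  rownames(out) <- NULL
  out
}

#' Descriptive associations between self-reported mood and clinical ratings
#'
#' Joins back-filled ratings with same-day self-assessments and reports
#' Pearson correlations (with p values) for (mood, HDRS total),
#' (mood, YMRS total) and (HDRS total, YMRS total).
#'
#' @param assessments,ratings cohort tables.
#' @param window rating validity look-back in days.
#' @return data.frame with columns `pair`, `r`, `p`, `n` (`r`/`p` are `NA`
#'   when a member of the pair is constant).
#' @export
descriptive_association <- function(assessments, ratings, window = 3) {
  targets <- backfill_ratings(
    ratings[c("subject_id", "date", "hdrs_total", "ymrs_total")],
    window = window)
  joined <- merge(targets, assessments[c("subject_id", "date", "mood")],
                  by = c("subject_id", "date"))
  joined <- joined[stats::complete.cases(
    joined[c("mood", "hdrs_total", "ymrs_total")]), ]
  if (nrow(joined) < 3) stop("fewer than 3 joined observations")
  pairs <- list(c("mood", "hdrs_total"), c("mood", "ymrs_total"),
                c("hdrs_total", "ymrs_total"))
  do.call(rbind, lapply(pairs, function(pr) {
    x <- joined[[pr[1]]]
    y <- joined[[pr[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(pair = paste(pr, collapse = " vs "),
                        r = NA_real_, p = NA_real_, n = length(x)))
    ct <- stats::cor.test(x, y)
    data.frame(pair = paste(pr, collapse = " vs "),
               r = unname(ct$estimate), p = ct$p.value, n = length(x))
  }))
}
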