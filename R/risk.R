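#' Relapse risk as posterior predictive exceedance probability
#'
#' The probability that an unobserved rating exceeds a clinical threshold,
#' `Pr(ytilde >= T)`, estimated as the fraction of posterior predictive
#' draws at or above `T`. With `T = 13` — the criterion for a depressive or
#' manic episode on the HDRS/YMRS total scales — it reads as a daily,
#' personal risk-of-relapse score. Defined for total-score models; item-1
#' scales never reach 13.
#'
#' @param draws posterior predictive draws, a matrix of `n_draws` rows by
#'   observations ([posterior_predict()] output). At least 100 draws per
#'   observation are recommended for a stable estimate.
#' @param threshold the clinical threshold `T` (default 13).
#' @return data.frame with one row per observation: `probability`,
#'   Monte-Carlo standard error `mc_se`, `n_draws`, `threshold`.
#' @export
exceedance_probability <- function(draws, threshold = 13) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n == 0) stop("no posterior predictive draws supplied")
  p <- colMeans(draws >= threshold)
  data.frame(probability = p, mc_se = sqrt(p * (1 - p) / n),
             n_draws = n, threshold = threshold)
}

#' Degenerate risk scores of the mean baselines
#'
#' Mean models carry no predictive distribution, so their risk score is the
#' binary indicator `1{yhat >= T}`: the pooled mean classifies every
#' instance identically (all low risk or all high risk, AUC 0.5 by
#' construction) and the separate mean classifies each individual by their
#' own observed mean.
#'
#' @param model a fitted [baseline_model()].
#' @param X design matrix in the fitted feature order.
#' @param subject_id subject per row.
#' @param threshold the clinical threshold `T` (default 13).
#' @return numeric vector of 0/1 scores.
#' @export
baseline_risk <- function(model, X, subject_id = NULL, threshold = 13) {
  as.numeric(predict(model, X, subject_id) >= threshold)
}

#' ROC curve and AUC of risk scores
#'
#' Evaluates risk scores as a binary classifier of true episodes
#' (`y >= T` constituting the positive class) with a threshold-sweep ROC
#' curve and trapezoidal AUC; ties are handled so the AUC equals the
#' rank-based (Mann-Whitney) probability of correct ordering. Higher scores
#' must indicate higher risk — the direction is fixed, never auto-flipped,
#' so a worse-than-chance classifier scores below 0.5.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return object of class `roc_result`: `points` (FPR/TPR, monotone from
#'   (0,0) to (1,1)), `auc`, and counts per class.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (length(unique(labels)) < 2)
    stop("labels must contain both classes")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  structure(list(points = pts, auc = as.numeric(pROC::auc(r)),
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0),
                 positive = "y >= threshold"), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC =", round(x$auc, 3),
      sprintf("(%d positive / %d negative)\n", x$n_pos, x$n_neg))
  invisible(x)
}
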