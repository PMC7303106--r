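#' Published reference weight table
#'
#' The posterior summaries of the population-level parameters (weight means
#' mu with 95% credible intervals and absolute t-statistics, and
#' between-subject SDs tau) published for the original MONARCA II cohort's
#' HDRS-total and YMRS-total models, shipped as plain CSV under
#' `inst/extdata`. Useful as worked examples for the variable-importance
#' computation and as realistic simulator ground truth.
#'
#' @param target `"hdrs_total"` or `"ymrs_total"`.
#' @return data.frame with one row per predictor (intercept first, then
#'   sorted by `abs_t` descending).
#' @export
reference_weight_table <- function(target = c("hdrs_total", "ymrs_total")) {
  target <- match.arg(target)
  f <- system.file("extdata",
                   paste0("reference_weights_", sub("_total$", "", target),
                          "_total.csv"),
                   package = "moodcast", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Reference population weights
#'
#' Population-level posterior summaries (means mu and between-subject SDs
#' tau of the regression weights, on normalised features) reported for the
#' MONARCA II cohort's HDRS-total and YMRS-total hierarchical models. They
#' serve as realistic default ground-truth parameters for the simulator.
#'
#' @param target `"hdrs_total"` or `"ymrs_total"`.
#' @return list with named vectors `mu` and `tau` (intercept first, then
#'   features in registry order) and residual SD `sigma`.
#' @export
reference_weights <- function(target = c("hdrs_total", "ymrs_total")) {
  target <- match.arg(target)
  feats <- feature_registry("all")
  if (target == "hdrs_total") {
    mu <- c(intercept = 6.43, activity = 0.53, alcohol = 0.59, anxiety = 2.26,
            irritability = 0.05, cognitive = 1.09, medicine_omitted = 0.52,
            medicine_changed = -1.81, mixed_mood = 2.11, mood_negative = -9.11,
            mood_positive = -2.80, sleep_negative = -6.48, sleep_positive = 2.83,
            stress = 0.56)
    tau <- c(intercept = 4.10, activity = 0.50, alcohol = 0.41, anxiety = 0.38,
             irritability = 0.59, cognitive = 0.43, medicine_omitted = 0.37,
             medicine_changed = 0.35, mixed_mood = 0.44, mood_negative = 0.56,
             mood_positive = 0.42, sleep_negative = 0.42, sleep_positive = 0.41,
             stress = 0.50)
    sigma <- 2.4
  } else {
    mu <- c(intercept = 3.10, activity = -0.78, alcohol = 0.05, anxiety = 0.18,
            irritability = 1.31, cognitive = 0.41, medicine_omitted = -0.02,
            medicine_changed = 0.46, mixed_mood = 1.02, mood_negative = 3.42,
            mood_positive = 12.83, sleep_negative = 0.30, sleep_positive = -2.69,
            stress = 1.15)
    tau <- c(intercept = 4.35, activity = 0.63, alcohol = 0.39, anxiety = 0.69,
             irritability = 0.71, cognitive = 0.94, medicine_omitted = 0.41,
             medicine_changed = 0.80, mixed_mood = 0.54, mood_negative = 0.66,
             mood_positive = 0.57, sleep_negative = 0.43, sleep_positive = 0.40,
             stress = 1.24)
    sigma <- 2.1
  }
  ord <- c("intercept", feats)
  list(mu = mu[ord], tau = tau[ord], sigma = sigma)
}

#' Simulation configuration
#'
#' Defines a synthetic cohort with the structure of the MONARCA II
#' smartphone-monitoring study: daily self-assessments over a 9-month
#' follow-up and up to five scheduled clinical evaluations per subject.
#' Ratings on visit days are generated from a ground-truth hierarchical
#' linear model on the engineered features, so downstream inference can be
#' checked against known parameters.
#'
#' @param n_subjects number of subjects (default 84).
#' @param n_days study length in days (default 270, a 9-month follow-up).
#' @param n_visits scheduled clinical evaluations per subject (default 5:
#'   baseline, 4 weeks, 3, 6 and 9 months).
#' @param missing_rate probability a day's self-assessment is absent
#'   entirely (default 0.3, giving roughly 190 entries per subject).
#' @param item_missing_rate probability an individual optional item is
#'   missing within an otherwise completed assessment (default 0.02).
#' @param item_noise nonnegative dispersion of item responses around the
#'   latent mood state (default 1).
#' @param mu_true,tau_true ground-truth population weight means/SDs,
#'   length 14 (intercept + 13 features in registry order). Defaults are
#'   the HDRS-total reference weights.
#' @param sigma_true ground-truth residual SD of ratings.
#' @param visit_attend_prob probability each scheduled visit is attended
#'   (default 0.7, reproducing roughly 3.3 evaluations per subject).
#' @param visit_jitter visits are shifted uniformly by up to this many days
#'   (default 3), so rating validity windows can occasionally overlap.
#' @param clip round simulated ratings and clip them to scale bounds
#'   (default TRUE); parameter-recovery studies disable this.
#' @param start_date first study day.
#' @param seed integer RNG seed; the cohort is fully deterministic given it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 84, n_days = 270, n_visits = 5,
                       missing_rate = 0.3, item_missing_rate = 0.02,
                       item_noise = 1,
                       mu_true = reference_weights("hdrs_total")$mu,
                       tau_true = reference_weights("hdrs_total")$tau,
                       sigma_true = reference_weights("hdrs_total")$sigma,
                       visit_attend_prob = 0.7, visit_jitter = 3,
                       clip = TRUE, start_date = as.Date("2015-01-01"),
                       seed = 1L) {
  p1 <- length(feature_registry("all")) + 1L
  stopifnot(n_subjects >= 1, n_days >= 1, n_visits >= 1,
            missing_rate >= 0, missing_rate <= 1,
            item_missing_rate >= 0, item_missing_rate <= 1,
            item_noise >= 0, sigma_true >= 0, all(tau_true >= 0),
            visit_attend_prob >= 0, visit_attend_prob <= 1,
            length(mu_true) == p1, length(tau_true) == p1)
  if (n_visits * 4 > n_days)
    stop("infeasible config: n_visits * 4 exceeds n_days")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_days = as.integer(n_days), n_visits = as.integer(n_visits),
                 missing_rate = missing_rate,
                 item_missing_rate = item_missing_rate,
                 item_noise = item_noise, mu_true = mu_true,
                 tau_true = tau_true, sigma_true = sigma_true,
                 visit_attend_prob = visit_attend_prob,
                 visit_jitter = as.integer(visit_jitter), clip = clip,
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "sim_config")
}

# snap continuous mood to the allowed response grid (nearest value)
.snap_mood <- function(x) {
  g <- mood_grid()
  g[max.col(-abs(outer(x, g, "-")), ties.method = "first")]
}

# derive an item-1 (mood item) score from a total score; keeps item1 <= total
.item1_from_total <- function(total, total_max) {
  t <- pmin(pmax(round(total), 0), total_max)
  pmin(pmax(round(t / 8), 0), 4)
}

#' Generate a synthetic cohort
#'
#' Each subject carries a slowly varying latent mood state (an AR(1)
#' process plus a subject-level offset; positive values read as manic,
#' negative as depressed) that drives all daily item responses within their
#' declared ranges. On attended visit days the engineered feature vector is
#' computed with the same transforms as the preprocessing module (sleep
#' centred on the subject's own mean over all simulated days) and the HDRS
#' and YMRS totals are drawn from the ground-truth hierarchical linear
#' model `y = alpha_j + beta_j' x + Normal(0, sigma)`, rounded and clipped
#' to scale bounds unless `config$clip` is FALSE. Item-1 scores are derived
#' from the totals. Whole-day and per-item missingness are applied last.
#'
#' @param config a [sim_config()].
#' @return list with `assessments` (data.frame of daily self-assessments),
#'   `ratings` (data.frame of clinical ratings) and `truth` (ground-truth
#'   parameters: `mu_true`, `tau_true`, `sigma_true`, per-subject
#'   `alpha_true` and `beta_true` for the primary HDRS-total model, and a
#'   `ymrs` list with the same structure).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  feats <- feature_registry("all")
  P <- length(feats)
  J <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(J))
  ymrs_ref <- reference_weights("ymrs_total")

  # per-subject ground-truth regression parameters
  par_h <- matrix(sapply(seq_len(P + 1), function(p)
    stats::rnorm(J, config$mu_true[p], config$tau_true[p])), nrow = J)
  par_y <- matrix(sapply(seq_len(P + 1), function(p)
    stats::rnorm(J, ymrs_ref$mu[p], ymrs_ref$tau[p])), nrow = J)
  dimnames(par_h) <- dimnames(par_y) <- list(ids, c("intercept", feats))

  phi <- 0.97
  assess <- vector("list", J)
  rate <- vector("list", J)
  for (j in seq_len(J)) {
    nd <- config$n_days
    # latent mood state: subject offset + stationary AR(1)
    m_j <- stats::rnorm(1, 0, 0.7)
    e <- stats::rnorm(nd)
    s <- numeric(nd)
    s[1] <- e[1]
    for (t in 2:nd) s[t] <- phi * s[t - 1] + sqrt(1 - phi^2) * e[t]
    L <- m_j + s
    sev <- abs(L)
    k <- config$item_noise

    mood <- .snap_mood(0.55 * L + 0.35 * k * stats::rnorm(nd))
    activity <- as.integer(pmin(3, pmax(-3, round(0.7 * L + 0.5 * k * stats::rnorm(nd)))))
    sleep_base <- stats::rnorm(1, 7.5, 0.6)
    sleep <- round(pmin(24, pmax(0, sleep_base - 1.1 * L +
                                   0.6 * k * stats::rnorm(nd))), 1)
    ord3 <- function(x, c1, c2) ifelse(x < c1, 0L, ifelse(x < c2, 1L, 2L))
    anxiety <- ord3(0.7 * sev + 0.5 * k * stats::rnorm(nd), 0.8, 1.5)
    irritability <- ord3(0.7 * sev + 0.5 * k * stats::rnorm(nd), 0.9, 1.6)
    cognitive <- ord3(0.7 * sev + 0.5 * k * stats::rnorm(nd), 1.0, 1.7)
    stress <- ord3(0.7 * sev + 0.5 * k * stats::rnorm(nd), 0.85, 1.55)
    alcohol <- pmin(10L, stats::rpois(nd, 0.5 + 0.25 * pmax(L, 0)))
    medicine <- sample(c("taken", "omitted", "changed"), nd, replace = TRUE,
                       prob = c(0.85, 0.08, 0.07))
    mixed_mood <- stats::rbinom(nd, 1, stats::plogis(-3.2 + 1.1 * sev))

    day <- data.frame(subject_id = ids[j],
                      date = config$start_date + 0:(nd - 1),
                      activity = activity, alcohol = alcohol,
                      anxiety = anxiety, irritability = irritability,
                      cognitive = cognitive, medicine = medicine,
                      mixed_mood = mixed_mood, mood = mood,
                      sleep_hours = sleep, stress = stress,
                      stringsAsFactors = FALSE)

    # visit schedule: protocol-like spacing for 5 visits, else even spread
    base_days <- if (config$n_visits == 5)
      pmax(1, round(1 + (nd - 1) * c(0, 0.107, 1 / 3, 2 / 3, 1)))
    else round(seq(1, nd, length.out = config$n_visits))
    vdays <- base_days
    if (config$visit_jitter > 0)
      vdays <- vdays + sample(-config$visit_jitter:config$visit_jitter,
                              length(vdays), replace = TRUE)
    vdays <- sort(unique(pmin(nd, pmax(1, vdays))))
    attended <- vdays[stats::runif(length(vdays)) <= config$visit_attend_prob]

    if (length(attended)) {
      vis <- day[attended, , drop = FALSE]
      sm <- stats::setNames(mean(sleep), ids[j])
      X <- build_features(vis, sleep_means = sm, feature_set = "all")
      eps_h <- stats::rnorm(nrow(X), 0, config$sigma_true)
      eps_y <- stats::rnorm(nrow(X), 0, ymrs_ref$sigma)
      y_h <- par_h[j, 1] + drop(X %*% par_h[j, -1]) + eps_h
      y_y <- par_y[j, 1] + drop(X %*% par_y[j, -1]) + eps_y
      if (config$clip) {
        y_h <- as.numeric(pmin(pmax(round(y_h), 0), 52))
        y_y <- as.numeric(pmin(pmax(round(y_y), 0), 60))
      }
      rate[[j]] <- data.frame(subject_id = ids[j], date = vis$date,
                              hdrs_total = y_h, ymrs_total = y_y,
                              hdrs_item1 = as.integer(.item1_from_total(y_h, 52)),
                              ymrs_item1 = as.integer(.item1_from_total(y_y, 60)),
                              stringsAsFactors = FALSE)
    }

    # whole-day missingness, then sparse per-item missingness on optionals
    keep <- stats::runif(nd) >= config$missing_rate
    day <- day[keep, , drop = FALSE]
    if (nrow(day) && config$item_missing_rate > 0) {
      for (it in c("alcohol", "anxiety", "irritability", "cognitive",
                   "mixed_mood", "stress"))
        day[[it]][stats::runif(nrow(day)) < config$item_missing_rate] <- NA
    }
    assess[[j]] <- day
  }

  assessments <- do.call(rbind, assess)
  ratings <- do.call(rbind, rate[!vapply(rate, is.null, logical(1))])
  rownames(assessments) <- NULL
  if (!is.null(ratings)) rownames(ratings) <- NULL else
    ratings <- data.frame(subject_id = character(), date = as.Date(character()),
                          hdrs_total = numeric(), ymrs_total = numeric(),
                          hdrs_item1 = numeric(), ymrs_item1 = numeric())

  truth <- list(mu_true = config$mu_true, tau_true = config$tau_true,
                sigma_true = config$sigma_true,
                alpha_true = par_h[, 1], beta_true = par_h[, -1, drop = FALSE],
                ymrs = list(mu_true = ymrs_ref$mu, tau_true = ymrs_ref$tau,
                            sigma_true = ymrs_ref$sigma,
                            alpha_true = par_y[, 1],
                            beta_true = par_y[, -1, drop = FALSE]),
                features = feats, subjects = ids)
  list(assessments = assessments, ratings = ratings, truth = truth)
}
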