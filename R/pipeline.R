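#' Run configuration for the end-to-end pipeline
#'
#' Builds a validated configuration from a YAML file or a nested list.
#' Unspecified fields take package defaults; unknown fields and invalid
#' enum values are rejected with a message naming the field. All stage
#' randomness derives from the single root `seed`.
#'
#' @param config path to a YAML file, or a named list.
#' @param ... fields overriding the file/list values, e.g. `seed = 7`.
#' @return object of class `run_config`.
#' @export
run_config <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(config, list(...))
  defaults <- list(
    out_dir = "moodcast_run", seed = 1L,
    target_name = "hdrs_total", feature_set = "all",
    threshold = 13, cv_k = 20,
    sim = list(), priors = list(), sampler = list(chains = 2, warmup = 300,
                                                  draws = 500),
    models = c("hierarchical", "pooled_bayesian", "pooled_mean",
               "separate_mean", "pooled_l2", "separate_l2",
               "pooled_gbt", "separate_gbt"))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$target_name %in% c("hdrs_total", "ymrs_total", "hdrs_item1",
                              "ymrs_item1"))
    stop("invalid config field target_name: ", cfg$target_name)
  if (!cfg$feature_set %in% c("all", "mandatory", "mood"))
    stop("invalid config field feature_set: ", cfg$feature_set)
  known_models <- c("hierarchical", "pooled_bayesian", "pooled_mean",
                    "separate_mean", "pooled_l2", "separate_l2",
                    "pooled_gbt", "separate_gbt")
  if (!all(cfg$models %in% known_models))
    stop("invalid config field models: ",
         paste(setdiff(cfg$models, known_models), collapse = ", "))
  if (cfg$cv_k < 1) stop("invalid config field cv_k")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(cfg)[order(names(unclass(cfg)))], f)
  unname(tools::md5sum(f))
}

.stage_info <- function(cfg, stage, extra = list()) {
  info <- c(list(stage = stage, config_hash = .config_hash(cfg),
                 seed = cfg$seed,
                 version = as.character(utils::packageVersion("moodcast"))),
            extra)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(info, file.path(cfg$out_dir,
                                       paste0(stage, "_info.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(info)
}

.model_roster <- function(cfg) {
  sp <- do.call(sampler_spec,
                utils::modifyList(cfg$sampler, list(seed = cfg$seed)))
  pr <- do.call(prior_spec, cfg$priors)
  rost <- list(
    hierarchical = bayes_model("hierarchical", pr, sp),
    pooled_bayesian = bayes_model("pooled_bayesian", pr, sp),
    pooled_mean = baseline_model("pooled_mean"),
    separate_mean = baseline_model("separate_mean"),
    pooled_l2 = baseline_model("pooled_l2"),
    separate_l2 = baseline_model("separate_l2"),
    pooled_gbt = baseline_model("pooled_gbt", seed = cfg$seed),
    separate_gbt = baseline_model("separate_gbt", seed = cfg$seed))
  rost[cfg$models]
}

#' Pipeline stages
#'
#' Thin orchestration over the package's functions, each stage idempotent
#' given the seed and writing its artifacts (plus a JSON stamp with config
#' hash, seed and package version) under `out_dir`:
#' * `pipeline_simulate()` — generate and write a synthetic cohort;
#' * `pipeline_fit()` — fit the hierarchical model on the full dataset and
#'   write population draws and the variable-importance table;
#' * `pipeline_crossval()` — run the hold-one-evaluation-out
#'   cross-validation and write per-iteration metrics, per-row predictions
#'   and the hierarchical vs separate-mean comparison test;
#' * `pipeline_risk()` — turn the cross-validated predictions into relapse
#'   risk scores and ROC/AUC per model (reusing the cross-validation
#'   artifacts when present);
#' * `pipeline_report()` — write a markdown summary of all artifacts;
#' * `run_pipeline()` — all of the above in order.
#'
#' @param cfg a [run_config()].
#' @return each stage invisibly returns its main artifact.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(cfg) {
  sim <- do.call(sim_config,
                 utils::modifyList(cfg$sim, list(seed = cfg$seed + 101L)))
  cohort <- generate_cohort(sim)
  write_cohort(cohort$assessments, cohort$ratings,
               file.path(cfg$out_dir, "cohort"), truth = cohort$truth)
  .stage_info(cfg, "simulate",
              list(n_assessments = nrow(cohort$assessments),
                   n_ratings = nrow(cohort$ratings)))
  invisible(cohort)
}

.load_dataset <- function(cfg, eligibility) {
  cohort <- read_cohort(file.path(cfg$out_dir, "cohort"))
  assemble_dataset(cohort$assessments, cohort$ratings,
                   target_name = cfg$target_name,
                   feature_set = cfg$feature_set, eligibility = eligibility)
}

#' @rdname pipeline
#' @export
pipeline_fit <- function(cfg) {
  ds <- .load_dataset(cfg, min_rows(2))
  sp <- do.call(sampler_spec,
                utils::modifyList(cfg$sampler, list(seed = cfg$seed + 202L)))
  post <- fit_hierarchical(ds, do.call(prior_spec, cfg$priors), sp)
  imp <- variable_importance(post)
  utils::write.csv(imp, file.path(cfg$out_dir, "importance.csv"),
                   row.names = FALSE)
  draws <- data.frame(chain = post$chain,
                      draw = stats::ave(post$chain, post$chain,
                                        FUN = seq_along))
  pop <- cbind(mu = post$mu, tau = post$tau, sigma = post$sigma)
  colnames(pop) <- c(paste0("mu.", colnames(post$mu)),
                     paste0("tau.", colnames(post$tau)), "sigma")
  utils::write.csv(cbind(draws, pop),
                   file.path(cfg$out_dir, "population_draws.csv"),
                   row.names = FALSE)
  yhat <- point_predict(post, ds$X, ds$data$subject_id)
  .stage_info(cfg, "fit", list(
    n_rows = nrow(ds$data), n_subjects = length(ds$subjects),
    in_sample_r2 = predicted_r2(ds$data$y, yhat),
    in_sample_rmse = rmse(ds$data$y, yhat)))
  invisible(post)
}

#' @rdname pipeline
#' @export
pipeline_crossval <- function(cfg) {
  ds <- .load_dataset(cfg, min_visits(3))
  plan <- make_cv_plan(ds, cfg$cv_k, seed = cfg$seed + 303L)
  cv <- run_cv(.model_roster(cfg), ds, plan, threshold = cfg$threshold)
  utils::write.csv(cv$table, file.path(cfg$out_dir, "cv_results.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$predictions,
                   file.path(cfg$out_dir, "cv_predictions.csv"),
                   row.names = FALSE)
  if (all(c("hierarchical", "separate_mean") %in% cfg$models)) {
    cmp <- compare_models(cv, "hierarchical", "separate_mean", "r2")
    jsonlite::write_json(cmp, file.path(cfg$out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  .stage_info(cfg, "crossval", list(K = cfg$cv_k))
  invisible(cv)
}

#' @rdname pipeline
#' @export
pipeline_risk <- function(cfg) {
  pf <- file.path(cfg$out_dir, "cv_predictions.csv")
  if (!file.exists(pf)) pipeline_crossval(cfg)
  preds <- utils::read.csv(pf, stringsAsFactors = FALSE)
  utils::write.csv(
    preds[c("model", "subject_id", "date", "risk")],
    file.path(cfg$out_dir, "risk_scores.csv"), row.names = FALSE)
  rocs <- lapply(split(preds, preds$model), function(d) {
    lab <- d$y >= cfg$threshold
    if (length(unique(lab)) < 2) return(NULL)
    roc_auc(d$risk, lab)
  })
  rocs <- rocs[!vapply(rocs, is.null, logical(1))]
  auc <- lapply(rocs, function(r) r$auc)
  jsonlite::write_json(auc, file.path(cfg$out_dir, "auc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pts <- do.call(rbind, lapply(names(rocs), function(m)
    cbind(model = m, rocs[[m]]$points)))
  utils::write.csv(pts, file.path(cfg$out_dir, "roc_points.csv"),
                   row.names = FALSE)
  .stage_info(cfg, "risk", list(threshold = cfg$threshold))
  invisible(rocs)
}

#' @rdname pipeline
#' @export
pipeline_report <- function(cfg) {
  od <- cfg$out_dir
  lines <- c("# moodcast run report", "",
             sprintf("- target: %s, features: %s, seed: %d",
                     cfg$target_name, cfg$feature_set, cfg$seed), "")
  cohort <- read_cohort(file.path(od, "cohort"))
  assoc <- descriptive_association(cohort$assessments, cohort$ratings)
  lines <- c(lines, "## Descriptive associations (day level)", "",
             utils::capture.output(print(assoc, row.names = FALSE)), "")
  impf <- file.path(od, "importance.csv")
  if (file.exists(impf)) {
    imp <- utils::read.csv(impf)
    lines <- c(lines, "## Variable importance (population weights)", "",
               utils::capture.output(print(
                 imp[c("predictor", "mean", "sd", "abs_t")],
                 row.names = FALSE, digits = 3)), "")
  }
  cvf <- file.path(od, "cv_results.csv")
  if (file.exists(cvf)) {
    cv <- utils::read.csv(cvf)
    agg <- stats::aggregate(cbind(r2, rmse) ~ model, cv, mean)
    lines <- c(lines, sprintf("## Cross-validation (K = %d)", cfg$cv_k), "",
               utils::capture.output(print(agg, row.names = FALSE,
                                           digits = 3)), "")
  }
  aucf <- file.path(od, "auc.json")
  if (file.exists(aucf)) {
    auc <- jsonlite::read_json(aucf)
    lines <- c(lines, "## Relapse-risk classification (AUC)", "",
               sprintf("- %s: %.3f", names(auc), unlist(auc)), "")
  }
  out <- file.path(od, "report.md")
  writeLines(lines, out)
  .stage_info(cfg, "report")
  invisible(out)
}

#' @rdname pipeline
#' @export
run_pipeline <- function(cfg) {
  pipeline_simulate(cfg)
  pipeline_fit(cfg)
  pipeline_crossval(cfg)
  pipeline_risk(cfg)
  pipeline_report(cfg)
}
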