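test_that("predicted R2 and RMSE match hand-computed oracles", {
  y <- c(0, 0, 13, 13)
  yhat <- c(0, 13, 0, 13)
  expect_equal(rmse(y, yhat), 13 / sqrt(2))
  # SS_res = 2 * 169, SS_tot = 4 * 6.5^2 = 169 -> R2 = -1
  expect_equal(predicted_r2(y, yhat), -1)
  expect_equal(predicted_r2(y, y), 1)
  expect_equal(rmse(y, y), 0)
  expect_equal(predicted_r2(y, rep(mean(y), 4)), 0)
  expect_true(is.na(predicted_r2(c(2, 2, 2), c(1, 2, 3))))
})

test_that("cv plans hold one whole evaluation window per subject", {
  co <- tiny_cohort(seed = 41, n_subjects = 4, n_days = 60, n_visits = 4)
  ds <- assemble_dataset(co$assessments, co$ratings, "hdrs_total", "all",
                         min_visits(3))
  plan <- make_cv_plan(ds, K = 1, seed = 1)
  expect_equal(nrow(plan$held_out), length(ds$subjects))
  plan5 <- make_cv_plan(ds, K = 5, seed = 2)
  for (k in 1:5) {
    hk <- plan5$held_out[plan5$held_out$iteration == k, ]
    expect_equal(hk$subject_id, sort(ds$subjects))
    test_rows <- paste(ds$data$subject_id, ds$data$visit_date) %in%
      paste(hk$subject_id, hk$visit_date)
    # the full validity window moves together; train/test row-disjoint
    expect_true(all(tapply(test_rows, paste(ds$data$subject_id,
                                            ds$data$visit_date),
                           function(v) all(v) || !any(v))))
    expect_gt(sum(test_rows), 0)
    expect_lt(sum(test_rows), nrow(ds$data))
  }
  expect_identical(make_cv_plan(ds, 5, seed = 2)$held_out, plan5$held_out)
})

test_that("held-out visits are sampled uniformly", {
  co <- tiny_cohort(seed = 43, n_subjects = 1, n_days = 40, n_visits = 3)
  ds <- assemble_dataset(co$assessments, co$ratings, "hdrs_total", "all",
                         min_visits(3))
  plan <- make_cv_plan(ds, K = 300, seed = 3)
  counts <- table(plan$held_out$visit_date)
  expect_equal(length(counts), 3)
  expect_gt(chisq.test(counts)$p.value, 1e-4)
})

test_that("plans reject subjects with too few evaluations", {
  co <- tiny_cohort(seed = 44, n_subjects = 2, n_days = 40, n_visits = 4)
  keep2 <- co$ratings[co$ratings$subject_id != "S001" |
                        !duplicated(co$ratings$subject_id), ]
  ds <- assemble_dataset(co$assessments, keep2, "hdrs_total", "all",
                         min_rows(1))
  expect_error(make_cv_plan(ds, 5), "fewer than 3.*S001")
})

test_that("a single-model cv run yields exactly K metric rows", {
  co <- tiny_cohort(seed = 45, n_subjects = 4, n_days = 60, n_visits = 4)
  ds <- assemble_dataset(co$assessments, co$ratings, "hdrs_total", "all",
                         min_visits(3))
  plan <- make_cv_plan(ds, K = 4, seed = 4)
  cv <- run_cv(list(pooled_mean = baseline_model("pooled_mean")), ds, plan)
  expect_equal(nrow(cv$table), 4)
  expect_true(all(cv$table$model == "pooled_mean"))
  expect_true(all(cv$table$rmse >= 0))
  expect_true(all(cv$table$r2 <= 1, na.rm = TRUE))
  # pooled mean hovers at zero predicted R2 by construction
  expect_lte(mean(cv$table$r2, na.rm = TRUE), 0.05)
  expect_null(cv$failures)
})

test_that("model comparison handles degenerate and regular cases", {
  fake_cv <- function(a, b) {
    structure(list(table = data.frame(
      iteration = rep(seq_along(a), 2), model = rep(c("A", "B"),
                                                    each = length(a)),
      r2 = c(a, b), rmse = 1)), class = "cv_result")
  }
  eq <- compare_models(fake_cv(rep(0.5, 10), rep(0.5, 10)), "A", "B", "r2")
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)
  sep <- compare_models(fake_cv(rep(0, 10), rep(1, 10)), "A", "B", "r2")
  expect_equal(sep$statistic, -Inf)
  expect_equal(sep$p.value, 0)
  expect_error(compare_models(fake_cv(0.1, 0.2), "A", "B", "r2"),
               "at least 2")
})

test_that("the t test holds its nominal type-I error under the null", {
  set.seed(46)
  reject <- replicate(1000, {
    tt <- t.test(rnorm(20), rnorm(20), var.equal = FALSE)
    tt$p.value < 0.05
  })
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("importance |t| reproduces the published worked examples", {
  hdrs <- reference_weight_table("hdrs_total")
  ymrs <- reference_weight_table("ymrs_total")
  mn <- hdrs[hdrs$predictor == "mood_negative", ]
  expect_equal(importance_t(mn$mu_mean, mn$mu_sd), 6.51, tolerance = 0.01)
  mp <- ymrs[ymrs$predictor == "mood_positive", ]
  expect_equal(importance_t(mp$mu_mean, mp$mu_sd), 6.75, tolerance = 0.01)
})

test_that("importance tables sort by |t| and summarise the posterior", {
  set.seed(47)
  mu <- cbind(intercept = rnorm(2000, 6, 1), f1 = rnorm(2000, -3, 0.5),
              f2 = rnorm(2000, 0, 1))
  post <- structure(list(mu = mu, tau = abs(mu) / 2),
                    class = "posterior_samples")
  imp <- variable_importance(post)
  expect_equal(imp$predictor[1:2], c("f1", "intercept"))
  expect_equal(imp$abs_t, abs(imp$mean) / imp$sd)
  expect_true(all(imp$ci_low <= imp$mean & imp$mean <= imp$ci_high))
  # symmetric-about-zero draws carry no importance
  expect_lt(imp$abs_t[imp$predictor == "f2"], 0.1)
  expect_true(all(c("tau_mean", "tau_sd") %in% names(imp)))
})

test_that("descriptive associations recover signs and reject tiny inputs", {
  grid <- c(-3, -2, -1, -0.5, 0, 0.5, 1, 2, 3)
  days <- as.Date("2020-01-01") + 0:99
  mood <- rep(grid, length.out = 100)
  a <- data.frame(subject_id = "s", date = days, mood = mood)
  r <- data.frame(subject_id = "s", date = days,
                  hdrs_total = 20 - 5 * mood, ymrs_total = 10 + 3 * mood)
  out <- descriptive_association(a, r)
  expect_equal(out$r[out$pair == "mood vs hdrs_total"], -1)
  expect_equal(out$r[out$pair == "mood vs ymrs_total"], 1)
  # constant column is reported missing
  r$ymrs_total <- 5
  out2 <- descriptive_association(a, r)
  expect_true(is.na(out2$r[out2$pair == "mood vs ymrs_total"]))
  expect_error(descriptive_association(a[1:2, ], r[1:2, ]), "fewer than 3")
  # independent pairs: negligible correlation at n = 1000
  set.seed(48)
  days2 <- as.Date("2020-01-01") + 0:999
  a2 <- data.frame(subject_id = "s", date = days2,
                   mood = sample(grid, 1000, TRUE))
  r2 <- data.frame(subject_id = "s", date = days2,
                   hdrs_total = sample(0:30, 1000, TRUE),
                   ymrs_total = sample(0:30, 1000, TRUE))
  out3 <- descriptive_association(a2, r2)
  expect_true(all(abs(out3$r) < 0.1))
})
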