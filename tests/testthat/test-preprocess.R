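mk_ratings <- function(subject, days, values = seq_along(days) * 0 + 10) {
  data.frame(subject_id = rep(subject, length(days)),
             date = as.Date("2020-01-01") + days - 1, hdrs_total = values)
}

test_that("one rating expands to the visit day and 3 previous days", {
  out <- backfill_ratings(mk_ratings("a", 10))
  expect_equal(out$date, as.Date("2020-01-01") + 6:9)
  expect_equal(unique(out$visit_date), as.Date("2020-01-10"))
  expect_equal(nrow(out), 4)
})

test_that("overlapping windows resolve to the nearest visit", {
  out <- backfill_ratings(mk_ratings("a", c(10, 12), values = c(1, 2)))
  expect_false(any(duplicated(out[c("subject_id", "date")])))
  day9 <- out[out$date == as.Date("2020-01-09"), ]
  expect_equal(day9$hdrs_total, 1)  # day 9 is nearer visit 10 than visit 12
  day10 <- out[out$date == as.Date("2020-01-10"), ]
  expect_equal(day10$hdrs_total, 1)
  day11 <- out[out$date == as.Date("2020-01-11"), ]
  expect_equal(day11$hdrs_total, 2)
})

test_that("empty ratings give an empty table", {
  out <- backfill_ratings(mk_ratings("a", integer(0)))
  expect_equal(nrow(out), 0)
  expect_true(all(c("subject_id", "date", "visit_date") %in% names(out)))
})

test_that("expansion never exceeds 4 rows per rating", {
  set.seed(33)
  for (rep in 1:10) {
    r <- mk_ratings("a", sort(sample(1:60, 8)))
    r <- rbind(r, mk_ratings("b", sort(sample(1:60, 5))))
    out <- backfill_ratings(r)
    expect_lte(nrow(out), 4 * nrow(r))
    expect_false(any(duplicated(out[c("subject_id", "date")])))
    expect_true(all(out$visit_date - out$date <= 3 & out$visit_date >= out$date))
  }
})

test_that("assembled row count matches a brute-force join oracle", {
  co <- tiny_cohort(seed = 19, n_subjects = 3, n_days = 50, n_visits = 4)
  ds <- assemble_dataset(co$assessments, co$ratings, "hdrs_total", "all",
                         min_rows(1))
  # oracle: enumerate days, attribute each to its nearest covering rating,
  # count those with a complete same-day assessment
  expected <- 0
  for (s in unique(co$ratings$subject_id)) {
    r <- co$ratings[co$ratings$subject_id == s, ]
    a <- co$assessments[co$assessments$subject_id == s, ]
    days <- sort(unique(unlist(lapply(r$date, function(d) as.list(d - 3:0)))))
    for (d in days) {
      cand <- r$date[r$date >= d & r$date <= d + 3]
      if (!length(cand)) next
      if (as.Date(d, origin = "1970-01-01") %in% a$date) {
        row <- a[a$date == d, ]
        if (!anyNA(row)) expected <- expected + 1
      }
    }
  }
  expect_equal(nrow(ds$data), expected)
  # non-overlapping windows: row count is sum of min(4, covered days)
  expect_lte(nrow(ds$data), 4 * nrow(co$ratings))
})

test_that("feature sets control the design matrix width", {
  co <- tiny_cohort(seed = 5)
  ds_mood <- assemble_dataset(co$assessments, co$ratings, "hdrs_total",
                              "mood", min_rows(1))
  expect_equal(ncol(ds_mood$X), 2)
  ds_mand <- assemble_dataset(co$assessments, co$ratings, "hdrs_total",
                              "mandatory", min_rows(1))
  expect_equal(ncol(ds_mand$X), 7)
})

test_that("eligibility by distinct evaluations excludes sparse subjects", {
  co <- tiny_cohort(seed = 6, n_subjects = 2, n_days = 40, n_visits = 4)
  r <- co$ratings
  # cut one subject down to 2 visits
  drop <- which(r$subject_id == "S002")[seq_len(sum(r$subject_id == "S002") - 2)]
  r <- r[-drop, ]
  ds <- assemble_dataset(co$assessments, r, "hdrs_total", "all",
                         min_visits(3))
  expect_false("S002" %in% ds$subjects)
  expect_true("S001" %in% ds$subjects)
  expect_error(assemble_dataset(co$assessments, r[0, ], "hdrs_total", "all",
                                min_rows(1)))
})

test_that("duplicate same-day assessments keep the last-entered record", {
  co <- tiny_cohort(seed = 11, n_subjects = 1, n_days = 30, n_visits = 3)
  a <- co$assessments
  vis_day <- co$ratings$date[1]
  dup <- a[a$date == vis_day, ]
  dup$mood <- if (dup$mood == 0) 1 else 0
  a2 <- rbind(a, dup)  # later-entered correction appended at the end
  ds <- assemble_dataset(a2, co$ratings, "hdrs_total", "all", min_rows(1))
  got <- ds$raw[ds$raw$date == vis_day, "mood"]
  expect_equal(got, dup$mood)
})

test_that("rows with missing included items are dropped, not imputed", {
  co <- tiny_cohort(seed = 13, n_subjects = 2, n_days = 40, n_visits = 4)
  a <- co$assessments
  vis <- co$ratings$date[1]
  a$stress[a$subject_id == co$ratings$subject_id[1] & a$date == vis] <- NA
  ds_all <- assemble_dataset(a, co$ratings, "hdrs_total", "all", min_rows(1))
  expect_false(any(ds_all$data$subject_id == co$ratings$subject_id[1] &
                     ds_all$data$date == vis))
  # the mandatory set ignores stress, so the row stays
  ds_mand <- assemble_dataset(a, co$ratings, "hdrs_total", "mandatory",
                              min_rows(1))
  expect_true(any(ds_mand$data$subject_id == co$ratings$subject_id[1] &
                    ds_mand$data$date == vis))
})

test_that("held-out rows never influence training sleep features", {
  co <- tiny_cohort(seed = 17, n_subjects = 3, n_days = 50, n_visits = 4)
  ds <- assemble_dataset(co$assessments, co$ratings, "hdrs_total", "all",
                         min_rows(1))
  test_idx <- which(ds$data$visit_date == ds$data$visit_date[1] &
                      ds$data$subject_id == ds$data$subject_id[1])
  train_idx <- setdiff(seq_len(nrow(ds$data)), test_idx)
  keys <- ds$data[test_idx, c("subject_id", "date")]
  X1 <- moodcast:::.fold_features(ds, train_idx, keys)
  # mutate the held-out rows' sleep wildly; training features must not move
  ds2 <- ds
  sel <- paste(ds2$sleep_table$subject_id, ds2$sleep_table$date) %in%
    paste(keys$subject_id, keys$date)
  ds2$sleep_table$sleep_hours[sel] <- 23.5
  ds2$raw$sleep_hours[test_idx] <- 23.5
  X2 <- moodcast:::.fold_features(ds2, train_idx, keys)
  expect_identical(X1, X2)
  # without the exclusion the mutation would leak into the means
  X3 <- moodcast:::.fold_features(ds2, train_idx, NULL)
  expect_false(identical(X1, X3))
})
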