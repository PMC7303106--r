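#' Expand clinical ratings over their validity window
#'
#' A clinical rating reflects the days leading up to the evaluation, so each
#' rating is considered valid on the visit day and the `window` preceding
#' days (default 3, i.e. four days in total). When windows of two visits
#' overlap, a day is attributed to the nearer visit; exact ties go to the
#' later visit.
#'
#' @param ratings data.frame with columns `subject_id`, `date` and one or
#'   more target columns.
#' @param window number of days before the visit the rating remains valid.
#' @return data.frame with one row per (subject, day) carrying the columns
#'   of the attributed rating plus `visit_date`.
#' @export
backfill_ratings <- function(ratings, window = 3) {
  tcols <- setdiff(names(ratings), c("subject_id", "date"))
  if (!nrow(ratings)) {
    out <- ratings[0, , drop = FALSE]
    out$visit_date <- out$date
    return(out[c("subject_id", "date", "visit_date", tcols)])
  }
  ratings <- ratings[order(ratings$subject_id, ratings$date), , drop = FALSE]
  reps <- rep(seq_len(nrow(ratings)), each = window + 1)
  out <- ratings[reps, , drop = FALSE]
  out$visit_date <- out$date
  out$date <- out$date - rep(window:0, times = nrow(ratings))
  # overlap resolution: nearest visit wins, ties to the later visit
  dist <- as.integer(out$visit_date - out$date)
  ord <- order(out$subject_id, out$date, dist, -as.numeric(out$visit_date))
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out[c("subject_id", "date")]), , drop = FALSE]
  rownames(out) <- NULL
  out[c("subject_id", "date", "visit_date", tcols)]
}

# per-subject mean sleep over a sleep table (subject_id, date, sleep_hours),
# optionally excluding held-out (subject, date) keys; used for the centred
# sleep features and recomputed on training data only during CV
.sleep_means <- function(sleep_table, exclude_keys = NULL) {
  st <- sleep_table[!is.na(sleep_table$sleep_hours), , drop = FALSE]
  if (!is.null(exclude_keys) && nrow(exclude_keys)) {
    key <- paste(st$subject_id, st$date)
    st <- st[!key %in% paste(exclude_keys$subject_id, exclude_keys$date), ,
             drop = FALSE]
  }
  means <- tapply(st$sleep_hours, st$subject_id, mean)
  list(subject = stats::setNames(as.numeric(means), names(means)),
       population = mean(st$sleep_hours))
}

#' Assemble the modelling dataset
#'
#' Joins back-filled clinical ratings with completed daily self-assessments
#' on (subject, day), keeps complete cases for the items the feature set
#' needs (no imputation is performed), applies the subject eligibility rule
#' and builds the normalised design matrix. Duplicate same-day assessments
#' keep the last-entered record.
#'
#' @param assessments,ratings cohort tables (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param target_name one of `"hdrs_total"`, `"ymrs_total"`, `"hdrs_item1"`,
#'   `"ymrs_item1"`.
#' @param feature_set as in [feature_registry()].
#' @param eligibility `min_rows(k)` (subjects need at least k joined rows;
#'   k = 2 mirrors the full-data model fit) or `min_visits(k)` (at least k
#'   distinct clinical evaluations represented; k = 3 mirrors the
#'   cross-validation design).
#' @param window rating validity look-back in days (default 3).
#' @return an object of class `model_dataset`: a list with `data` (rows of
#'   subject, date, visit_date, y), design matrix `X`, the raw joined item
#'   table `raw`, the all-days `sleep_table` used for sleep means,
#'   `sleep_means`, and metadata.
#' @export
assemble_dataset <- function(assessments, ratings,
                             target_name = c("hdrs_total", "ymrs_total",
                                             "hdrs_item1", "ymrs_item1"),
                             feature_set = c("all", "mandatory", "mood"),
                             eligibility = min_rows(2), window = 3) {
  target_name <- match.arg(target_name)
  feature_set <- match.arg(feature_set)
  items <- items_for_feature_set(feature_set)

  a <- assessments[!duplicated(assessments[c("subject_id", "date")],
                               fromLast = TRUE), , drop = FALSE]
  targets <- backfill_ratings(ratings[c("subject_id", "date", target_name)],
                              window = window)
  joined <- merge(targets, a, by = c("subject_id", "date"))
  if (!nrow(joined))
    stop("no rows after joining ratings with self-assessments")
  complete <- stats::complete.cases(joined[items])
  joined <- joined[complete, , drop = FALSE]
  if (!nrow(joined))
    stop("no rows left after complete-case filtering on items: ",
         paste(items, collapse = ", "))

  keep <- eligibility(joined)
  joined <- joined[joined$subject_id %in% keep, , drop = FALSE]
  if (!nrow(joined))
    stop("no subjects satisfy the eligibility rule ",
         attr(eligibility, "label"))
  joined <- joined[order(joined$subject_id, joined$date), , drop = FALSE]
  rownames(joined) <- NULL

  sleep_table <- a[a$subject_id %in% keep,
                   c("subject_id", "date", "sleep_hours")]
  sm <- .sleep_means(sleep_table)
  X <- build_features(joined, sleep_means = sm$subject,
                      feature_set = feature_set,
                      pop_sleep_mean = sm$population)

  structure(list(
    data = data.frame(subject_id = joined$subject_id, date = joined$date,
                      visit_date = joined$visit_date,
                      y = joined[[target_name]], stringsAsFactors = FALSE),
    X = X, raw = joined, sleep_table = sleep_table, sleep_means = sm,
    target_name = target_name, feature_set = feature_set,
    features = feature_registry(feature_set),
    subjects = sort(unique(joined$subject_id)),
    eligibility = attr(eligibility, "label"), window = window),
    class = "model_dataset")
}

#' Subject eligibility rules
#'
#' `min_rows(k)` keeps subjects contributing at least `k` complete joined
#' rows; `min_visits(k)` keeps subjects with complete data from at least
#' `k` distinct clinical evaluations.
#'
#' @param k minimum count.
#' @return a filter function over the joined table, returning eligible
#'   subject ids.
#' @export
min_rows <- function(k) {
  f <- function(joined) {
    n <- table(joined$subject_id)
    names(n)[n >= k]
  }
  attr(f, "label") <- sprintf("min_rows(%d)", k)
  f
}

#' @rdname min_rows
#' @export
min_visits <- function(k) {
  f <- function(joined) {
    n <- tapply(as.numeric(joined$visit_date), joined$subject_id,
                function(v) length(unique(v)))
    names(n)[n >= k]
  }
  attr(f, "label") <- sprintf("min_visits(%d)", k)
  f
}

#' @export
print.model_dataset <- function(x, ...) {
  cat("<model_dataset>", nrow(x$data), "rows,", length(x$subjects),
      "subjects\n  target:", x$target_name, " features:", x$feature_set,
      sprintf("(%d)", ncol(x$X)), "\n  eligibility:", x$eligibility, "\n")
  invisible(x)
}

# rebuild the design matrix for a subset of rows under fold-specific sleep
# means; test_keys are (subject_id, date) pairs excluded from the means
.fold_features <- function(dataset, rows, test_keys = NULL) {
  sm <- .sleep_means(dataset$sleep_table, exclude_keys = test_keys)
  build_features(dataset$raw[rows, , drop = FALSE], sleep_means = sm$subject,
                 feature_set = dataset$feature_set,
                 pop_sleep_mean = sm$population)
}
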