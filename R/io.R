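#' Write a cohort to CSV files
#'
#' Writes `self_assessments.csv` and `clinical_ratings.csv` under `path`
#' (ISO-8601 dates, empty cell = missing) and, when ground truth is
#' supplied, `ground_truth.json` keyed by the canonical feature order.
#' Output is byte-stable: regenerating the same cohort reproduces
#' identical files.
#'
#' @param assessments,ratings data.frames as returned by [generate_cohort()].
#' @param path directory to write into (created if absent).
#' @param truth optional ground-truth list to persist alongside.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(assessments, ratings, path, truth = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(path, "self_assessments.csv")
  fr <- file.path(path, "clinical_ratings.csv")
  a <- assessments
  a$date <- format(a$date, "%Y-%m-%d")
  r <- ratings
  r$date <- format(r$date, "%Y-%m-%d")
  utils::write.csv(a, fa, row.names = FALSE, na = "")
  utils::write.csv(r, fr, row.names = FALSE, na = "")
  paths <- c(assessments = fa, ratings = fr)
  if (!is.null(truth)) {
    ft <- file.path(path, "ground_truth.json")
    tr <- truth
    tr$beta_true <- as.data.frame(tr$beta_true)
    tr$ymrs$beta_true <- as.data.frame(tr$ymrs$beta_true)
    jsonlite::write_json(tr, ft, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, truth = ft)
  }
  invisible(paths)
}

.assess_cols <- c("subject_id", "date", "activity", "alcohol", "anxiety",
                  "irritability", "cognitive", "medicine", "mixed_mood",
                  "mood", "sleep_hours", "stress")
.rating_cols <- c("subject_id", "date", "hdrs_total", "ymrs_total",
                  "hdrs_item1", "ymrs_item1")

# range checks used by read_cohort(); returns character description of the
# violation or NA
.check_assess_row <- function(r) {
  in_rng <- function(v, lo, hi) is.na(v) || (v >= lo && v <= hi)
  if (is.na(r$activity) || !in_rng(r$activity, -3, 3)) return("activity out of range")
  if (!in_rng(r$alcohol, 0, 10)) return("alcohol out of range")
  for (it in c("anxiety", "irritability", "cognitive", "stress"))
    if (!in_rng(r[[it]], 0, 2)) return(paste(it, "out of range"))
  if (is.na(r$medicine) || !r$medicine %in% c("taken", "omitted", "changed"))
    return("unknown medicine category")
  if (!in_rng(r$mixed_mood, 0, 1)) return("mixed_mood not binary")
  if (is.na(r$mood) || !any(abs(r$mood - mood_grid()) < 1e-9))
    return("mood off grid")
  if (is.na(r$sleep_hours) || !in_rng(r$sleep_hours, 0, 24))
    return("sleep_hours out of range")
  NA_character_
}

#' Read a cohort from CSV files
#'
#' Inverse of [write_cohort()]: reads and validates the two cohort CSVs,
#' reporting any malformed rows with their file line numbers.
#'
#' @param path directory containing `self_assessments.csv` and
#'   `clinical_ratings.csv`.
#' @return list with `assessments` and `ratings` data.frames.
#' @export
read_cohort <- function(path) {
  fa <- file.path(path, "self_assessments.csv")
  fr <- file.path(path, "clinical_ratings.csv")
  a <- utils::read.csv(fa, na.strings = "", stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character",
                                      medicine = "character",
                                      activity = "integer", alcohol = "integer",
                                      anxiety = "integer",
                                      irritability = "integer",
                                      cognitive = "integer",
                                      mixed_mood = "integer",
                                      mood = "numeric",
                                      sleep_hours = "numeric",
                                      stress = "integer"))
  r <- utils::read.csv(fr, na.strings = "", stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character",
                                      hdrs_total = "numeric",
                                      ymrs_total = "numeric",
                                      hdrs_item1 = "integer",
                                      ymrs_item1 = "integer"))
  if (!identical(names(a), .assess_cols))
    stop("self_assessments.csv: unexpected columns")
  if (!identical(names(r), .rating_cols))
    stop("clinical_ratings.csv: unexpected columns")
  a$date <- as.Date(a$date)
  r$date <- as.Date(r$date)

  bad <- character()
  if (nrow(a)) {
    for (i in seq_len(nrow(a))) {
      msg <- .check_assess_row(a[i, ])
      if (!is.na(msg) || is.na(a$date[i]))
        bad <- c(bad, sprintf("self_assessments.csv line %d: %s", i + 1L,
                              if (is.na(a$date[i])) "bad date" else msg))
    }
    if (anyDuplicated(a[c("subject_id", "date")]))
      stop("self_assessments.csv: duplicate subject/date records")
  }
  if (nrow(r)) {
    ok <- !is.na(r$date) & r$hdrs_total >= 0 & r$ymrs_total >= 0 &
      r$hdrs_item1 >= 0 & r$ymrs_item1 >= 0 &
      r$hdrs_item1 <= r$hdrs_total & r$ymrs_item1 <= r$ymrs_total
    if (any(!ok))
      bad <- c(bad, sprintf("clinical_ratings.csv line %d: invalid rating",
                            which(!ok) + 1L))
  }
  if (length(bad)) stop("malformed rows:\n", paste(bad, collapse = "\n"))
  list(assessments = a, ratings = r)
}
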