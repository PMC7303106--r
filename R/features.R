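#' Canonical feature registry
#'
#' The engineered predictors used by every model in the package, in a fixed
#' canonical order. Raw self-assessment items are transformed as follows:
#' mood is split into a non-positive and a non-negative component, sleep
#' duration is centred on the individual training mean and split the same
#' way, and the three-level medicine-adherence item is coded with two
#' exclusive dummies (the reference level, medicine taken as prescribed,
#' gets no column). All components are then normalised by their allowed
#' ranges so that every feature lies in \[-1, 1\].
#'
#' @param feature_set one of `"all"` (13 features), `"mandatory"`
#'   (the 7 features derived from the mandatory items: activity, medicine,
#'   mood and sleep) or `"mood"` (the 2 mood components only).
#' @return character vector of feature names in canonical order.
#' @export
feature_registry <- function(feature_set = c("all", "mandatory", "mood")) {
  feature_set <- match.arg(feature_set)
  all <- c("activity", "alcohol", "anxiety", "irritability", "cognitive",
           "medicine_omitted", "medicine_changed", "mixed_mood",
           "mood_negative", "mood_positive",
           "sleep_negative", "sleep_positive", "stress")
  switch(feature_set,
         all = all,
         mandatory = c("activity", "medicine_omitted", "medicine_changed",
                       "mood_negative", "mood_positive",
                       "sleep_negative", "sleep_positive"),
         mood = c("mood_negative", "mood_positive"))
}

#' Raw self-assessment items required for a feature set
#'
#' @param feature_set as in [feature_registry()].
#' @return character vector of raw item column names.
#' @export
items_for_feature_set <- function(feature_set = c("all", "mandatory", "mood")) {
  feature_set <- match.arg(feature_set)
  switch(feature_set,
         all = c("activity", "alcohol", "anxiety", "irritability",
                 "cognitive", "medicine", "mixed_mood", "mood",
                 "sleep_hours", "stress"),
         mandatory = c("activity", "medicine", "mood", "sleep_hours"),
         mood = "mood")
}

# allowed mood responses; the half points exist only around neutral
mood_grid <- function() c(-3, -2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Split mood into negative and positive components
#'
#' Self-reported mood (a score on the grid -3..+3 including -0.5 and +0.5)
#' is split so that depressive and elevated mood can carry separate
#' regression weights: `mood_negative = min(mood, 0)` and
#' `mood_positive = max(mood, 0)`.
#'
#' @param mood numeric vector of raw mood scores on the allowed grid.
#' @return a two-column matrix with columns `mood_negative`, `mood_positive`.
#' @export
split_mood <- function(mood) {
  ok <- is.na(mood) | vapply(mood, function(m)
    any(abs(m - mood_grid()) < 1e-9), logical(1))
  if (!all(ok))
    stop("mood value(s) off the allowed grid: ",
         paste(unique(mood[!ok]), collapse = ", "))
  cbind(mood_negative = pmin(mood, 0), mood_positive = pmax(mood, 0))
}

#' Centre and split sleep duration
#'
#' Sleep duration (hours) is centred on the individual's mean sleep computed
#' from training data only, then split into non-positive and non-negative
#' deviations so that reduced and increased sleep can carry separate
#' weights. Subjects absent from the training means fall back to the
#' population training mean (cold start).
#'
#' @param sleep_hours numeric vector, hours in \[0, 24\].
#' @param subject_mean numeric vector (recycled) of per-subject training
#'   means; `NA` entries use `pop_mean`.
#' @param pop_mean population training mean used as cold-start fallback.
#' @return a two-column matrix with columns `sleep_negative`, `sleep_positive`.
#' @export
center_split_sleep <- function(sleep_hours, subject_mean, pop_mean = NA_real_) {
  stopifnot(all(is.na(sleep_hours) | (sleep_hours >= 0 & sleep_hours <= 24)))
  m <- ifelse(is.na(subject_mean), pop_mean, subject_mean)
  d <- sleep_hours - m
  cbind(sleep_negative = pmin(d, 0), sleep_positive = pmax(d, 0))
}

#' Dummy-code the medicine adherence item
#'
#' The three-level categorical item (taken as prescribed / not taken /
#' taken with changes) is coded with two exclusive binary indicators;
#' the expected most common level, taken as prescribed, is the reference
#' and gets no column, avoiding the dummy-variable trap.
#'
#' @param category character vector with values in
#'   `c("taken", "omitted", "changed")`.
#' @return a two-column 0/1 matrix `medicine_omitted`, `medicine_changed`.
#' @export
encode_medicine <- function(category) {
  bad <- !is.na(category) & !category %in% c("taken", "omitted", "changed")
  if (any(bad))
    stop("unknown medicine category: ", paste(unique(category[bad]), collapse = ", "))
  cbind(medicine_omitted = as.numeric(category == "omitted"),
        medicine_changed = as.numeric(category == "changed"))
}

# divisors taking each engineered component onto [-1, 1]; sleep deviations
# have no hard bound, so they are scaled by 12 h and clipped
.norm_divisors <- c(activity = 3, alcohol = 10, anxiety = 2, irritability = 2,
                    cognitive = 2, medicine_omitted = 1, medicine_changed = 1,
                    mixed_mood = 1, mood_negative = 3, mood_positive = 3,
                    sleep_negative = 12, sleep_positive = 12, stress = 2)

#' Normalise an engineered feature matrix by allowed ranges
#'
#' Each component is divided by its maximum allowed magnitude: signed items
#' (activity, mood components) by 3; the 0-2 items by 2; alcohol units by 10;
#' sleep deviations by 12 h then clipped to \[-1, 1\]; binaries unchanged.
#'
#' @param raw numeric matrix whose columns are a subset of
#'   [feature_registry()] names, on the raw (pre-normalisation) scale.
#' @return matrix of the same shape with all values in \[-1, 1\].
#' @export
normalize_features <- function(raw) {
  raw <- as.matrix(raw)
  cn <- colnames(raw)
  if (is.null(cn) || !all(cn %in% names(.norm_divisors)))
    stop("normalize_features() requires canonical feature column names")
  out <- sweep(raw, 2, .norm_divisors[cn], "/")
  pmin(pmax(out, -1), 1)
}

#' Build the normalised design matrix from raw day-level records
#'
#' Applies the mood split, sleep centring/split, medicine dummy coding and
#' range normalisation to a table of raw self-assessment items, returning
#' columns in canonical registry order for the requested feature set.
#'
#' @param raw data.frame with a `subject_id` column plus the raw items named
#'   by [items_for_feature_set()].
#' @param sleep_means named numeric vector of per-subject training sleep
#'   means (names are subject ids); ignored unless sleep is in the set.
#' @param feature_set as in [feature_registry()].
#' @param pop_sleep_mean cold-start fallback for subjects missing from
#'   `sleep_means`.
#' @return numeric matrix, one row per input row, columns
#'   `feature_registry(feature_set)`.
#' @export
build_features <- function(raw, sleep_means = NULL,
                           feature_set = c("all", "mandatory", "mood"),
                           pop_sleep_mean = NA_real_) {
  feature_set <- match.arg(feature_set)
  feats <- feature_registry(feature_set)
  n <- nrow(raw)
  cols <- list()
  if ("mood_negative" %in% feats)
    cols <- c(cols, list(split_mood(raw$mood)))
  if ("sleep_negative" %in% feats) {
    sm <- if (is.null(sleep_means)) rep(NA_real_, n) else
      unname(sleep_means[as.character(raw$subject_id)])
    cols <- c(cols, list(center_split_sleep(raw$sleep_hours, sm, pop_sleep_mean)))
  }
  if ("medicine_omitted" %in% feats)
    cols <- c(cols, list(encode_medicine(raw$medicine)))
  direct <- intersect(c("activity", "alcohol", "anxiety", "irritability",
                        "cognitive", "mixed_mood", "stress"), feats)
  if (length(direct)) {
    dm <- as.matrix(raw[direct])
    colnames(dm) <- direct
    cols <- c(cols, list(dm))
  }
  X <- do.call(cbind, cols)
  normalize_features(X[, feats, drop = FALSE])
}
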