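#' Means of consecutive windows of slice scores
#'
#' For an ordered vector of per-slice probabilities, returns the mean of
#' every run of `window` consecutive entries, in order.
#'
#' @param scores numeric vector of ordered slice scores.
#' @param window window length (default 5).
#' @return Numeric vector of length `length(scores) - window + 1`.
#' @export
windowed_mean_scores <- function(scores, window = 5L) {
  n <- length(scores)
  window <- as.integer(window)
  if (window < 1L) abort("`window` must be positive")
  if (n < window) {
    abort(sprintf("need at least %d slices, got %d", window, n))
  }
  cs <- cumsum(c(0, scores))
  (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
}

#' Patient-level decision score
#'
#' The maximum over all `window`-length runs of consecutive slices of the
#' mean slice probability — the statistic on which the patient-level
#' decision is made.
#'
#' @inheritParams windowed_mean_scores
#' @return Scalar score, bounded by the minimum and maximum slice score.
#' @export
patient_score <- function(scores, window = 5L) {
  max(windowed_mean_scores(scores, window))
}

#' Patient-level decision scores for a prediction table
#'
#' @param predictions tibble `(patient_id, slice_index, score)`; slices are
#'   ordered by `slice_index` within each patient.
#' @param window window length (default 5).
#' @return Tibble `(patient_id, patient_score)`.
#' @export
patient_scores <- function(predictions, window = 5L) {
  predictions |>
    dplyr::arrange(.data$patient_id, .data$slice_index) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(patient_score = patient_score(.data$score, window),
                     .groups = "drop")
}

#' Youden's index
#'
#' `J = sensitivity + specificity - 1`.
#'
#' @param sensitivity,specificity fractions in `[0, 1]`.
#' @return J, in `[-1, 1]`.
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1)) {
    abort("sensitivity and specificity must lie in [0, 1]")
  }
  sensitivity + specificity - 1
}

#' Threshold maximizing Youden's index
#'
#' Sweeps every distinct observed score plus one sentinel above the maximum
#' as candidate thresholds under the decision rule `score >= threshold =>
#' positive`, and returns the candidate with the largest Youden's index.
#' Ties are broken towards the largest (most specific) threshold.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels aligned with `scores`; both classes must be
#'   present.
#' @return The selected threshold (scalar).
#' @export
select_threshold_max_youden <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("length mismatch")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("both classes must be present to select a threshold")
  }
  cand <- sort(unique(scores))
  cand <- c(cand, max(cand) + 1)  # sentinel: classify everything negative
  # tp(t) = positives with score >= t, fp(t) = negatives with score >= t
  ord <- order(scores)
  s_sorted <- scores[ord]
  l_sorted <- labels[ord]
  # for each candidate, number of observations with score < t
  below <- findInterval(cand, s_sorted, left.open = TRUE)
  pos_below <- cumsum(l_sorted)
  neg_below <- cumsum(1L - l_sorted)
  tp <- n_pos - ifelse(below == 0L, 0L, pos_below[pmax(below, 1L)])
  fp <- n_neg - ifelse(below == 0L, 0L, neg_below[pmax(below, 1L)])
  j <- tp / n_pos + (n_neg - fp) / n_neg - 1
  best <- max(j)
  if (best <= 0) {
    warn("no candidate threshold separates the classes (max Youden index <= 0)")
  }
  max(cand[j == best])
}

#' Learn the patient- and slice-level decision thresholds
#'
#' Both thresholds are learned exclusively from training-set predictions:
#' the patient threshold maximizes Youden's index over the training
#' patients' windowed-mean-maximum scores, the slice threshold over the raw
#' training slice scores.
#'
#' @param train_predictions training prediction tibble
#'   `(patient_id, slice_index, score)`.
#' @param train_slice_labels tibble `(patient_id, slice_index, label)`, e.g.
#'   from [expand_annotations()].
#' @param train_patient_labels tibble `(patient_id, patient_label)`.
#' @param window window length for the patient score.
#' @return An object of class `rpe_thresholds` with fields `theta_patient`,
#'   `theta_slice` and `window`.
#' @export
fit_thresholds <- function(train_predictions, train_slice_labels,
                           train_patient_labels, window = 5L) {
  pscores <- patient_scores(train_predictions, window) |>
    dplyr::inner_join(train_patient_labels, by = "patient_id")
  if (nrow(pscores) < nrow(patient_scores(train_predictions, window))) {
    abort("patient labels missing for some training patients")
  }
  slices <- dplyr::inner_join(train_predictions, train_slice_labels,
                              by = c("patient_id", "slice_index"))
  if (nrow(slices) != nrow(train_predictions)) {
    abort("slice labels do not align with training predictions")
  }
  structure(
    list(theta_patient = select_threshold_max_youden(pscores$patient_score,
                                                     pscores$patient_label),
         theta_slice = select_threshold_max_youden(slices$score,
                                                   slices$label),
         window = as.integer(window),
         n_train_patients = nrow(pscores),
         n_train_slices = nrow(slices)),
    class = "rpe_thresholds")
}

#' @export
print.rpe_thresholds <- function(x, ...) {
  cat(sprintf(
    "<rpe_thresholds> patient %.4f (window %d), slice %.4f  [fit on %d patients / %d slices]\n",
    x$theta_patient, x$window, x$theta_slice,
    x$n_train_patients, x$n_train_slices))
  invisible(x)
}

#' @describeIn fit_thresholds thresholds as a two-row tibble.
#' @param x an `rpe_thresholds` object.
#' @param ... unused.
#' @export
tidy.rpe_thresholds <- function(x, ...) {
  tibble(level = c("patient", "slice"),
         threshold = c(x$theta_patient, x$theta_slice),
         window = c(x$window, NA_integer_))
}

#' Save / load learned thresholds
#'
#' @param thresholds an `rpe_thresholds` object.
#' @param path JSON path.
#' @export
save_thresholds <- function(thresholds, path) {
  jsonlite::write_json(unclass(thresholds), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_thresholds
#' @export
load_thresholds <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(p, class = "rpe_thresholds")
}

theta_patient_of <- function(thresholds) {
  if (inherits(thresholds, "rpe_thresholds")) thresholds$theta_patient
  else as.numeric(thresholds)
}

theta_slice_of <- function(thresholds) {
  if (inherits(thresholds, "rpe_thresholds")) thresholds$theta_slice
  else as.numeric(thresholds)
}

#' Classify patients from their slice-score vectors
#'
#' A patient is positive iff the maximum windowed-mean score is at or above
#' the patient threshold (ties classify positive).
#'
#' @param predictions prediction tibble `(patient_id, slice_index, score)`.
#' @param thresholds an [fit_thresholds()] object or a bare numeric patient
#'   threshold.
#' @param window window length, taken from `thresholds` when available.
#' @return Tibble `(patient_id, patient_score, patient_label)`.
#' @export
classify_patients <- function(predictions, thresholds, window = NULL) {
  window <- window %||%
    (if (inherits(thresholds, "rpe_thresholds")) thresholds$window else 5L)
  theta <- theta_patient_of(thresholds)
  patient_scores(predictions, window) |>
    dplyr::mutate(patient_label = as.integer(.data$patient_score >= theta))
}

#' Finalize slice labels given the patient-level decisions
#'
#' Every slice of a patient classified negative is finalized negative,
#' regardless of its score; slices of positive patients are thresholded at
#' the slice-level threshold (`score >= theta_slice` => positive).
#'
#' @param predictions prediction tibble `(patient_id, slice_index, score)`.
#' @param thresholds an [fit_thresholds()] object (learned on training
#'   predictions only).
#' @param patient_labels optional tibble `(patient_id, patient_label)` of
#'   already-made patient decisions; computed via [classify_patients()] when
#'   omitted.
#' @return `predictions` with an integer `final_label` column appended.
#' @export
finalize_slice_labels <- function(predictions, thresholds,
                                  patient_labels = NULL) {
  if (is.null(patient_labels)) {
    patient_labels <- classify_patients(predictions, thresholds)
  }
  theta_s <- theta_slice_of(thresholds)
  out <- dplyr::left_join(
    predictions,
    dplyr::select(patient_labels, "patient_id", "patient_label"),
    by = "patient_id")
  if (anyNA(out$patient_label)) {
    abort("patient_labels missing for some predicted patients")
  }
  out |>
    dplyr::mutate(final_label = as.integer(
      .data$patient_label == 1L & .data$score >= theta_s)) |>
    dplyr::select(-"patient_label")
}
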