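#' Accuracy, sensitivity and specificity of binary predictions
#'
#' Sensitivity is the fraction of positive instances classified correctly,
#' specificity the fraction of negative instances classified correctly.
#' Ratios with a zero denominator are reported as `NA` with a warning,
#' never as 0 or 1.
#'
#' @param predicted,truth aligned integer 0/1 vectors.
#' @return One-row tibble `(accuracy, sensitivity, specificity, tp, fp, tn,
#'   fn)`.
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) abort("length mismatch")
  if (length(truth) == 0L) abort("empty input")
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  tp <- sum(predicted == 1L & truth == 1L)
  fp <- sum(predicted == 1L & truth == 0L)
  tn <- sum(predicted == 0L & truth == 0L)
  fn <- sum(predicted == 0L & truth == 1L)
  sens <- if (tp + fn == 0L) {
    warn("no positive instances; sensitivity undefined")
    NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0L) {
    warn("no negative instances; specificity undefined")
    NA_real_
  } else tn / (tn + fp)
  tibble(accuracy = (tp + tn) / length(truth),
         sensitivity = sens, specificity = spec,
         tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with half credit for ties: the
#' probability that a randomly chosen positive instance outscores a
#' randomly chosen negative one.  Delegated to \pkg{pROC}.
#'
#' @param scores numeric scores (higher means more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC as a fraction in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    abort("both classes must be present to compute AUROC")
  }
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0L, 1L), direction = "<",
                                 quiet = TRUE)))
}

#' Patient-level AUROC of the windowed-mean-maximum score
#'
#' The patient-level ROC curve is drawn by sweeping thresholds over the
#' maxima of the mean of `window` consecutive slice scores.
#'
#' @param predictions prediction tibble `(patient_id, slice_index, score)`.
#' @param patient_labels tibble `(patient_id, patient_label)`.
#' @param window window length (default 5).
#' @return AUROC as a fraction in `[0, 1]`.
#' @export
patient_roc_auc <- function(predictions, patient_labels, window = 5L) {
  d <- patient_scores(predictions, window) |>
    dplyr::inner_join(patient_labels, by = "patient_id")
  roc_auc(d$patient_score, d$patient_label)
}

#' Summarize evaluation metrics over cross-validation iterations
#'
#' @param metrics tibble with columns `iteration_id`, `level` and the metric
#'   columns `accuracy`, `sensitivity`, `specificity`, `auroc` (fractions).
#' @param expected_n expected number of iterations per level (30 for the
#'   full repeated five-fold protocol); a differing count triggers a
#'   warning, and `NA` metric values are dropped with a warning.
#' @return Tibble `(level, metric, mean, sd, median, n, summary)` where
#'   `summary` is the percent-scale "mean ± SD/median" label.
#' @export
aggregate_iterations <- function(metrics, expected_n = 30L) {
  long <- metrics |>
    tidyr::pivot_longer(cols = dplyr::any_of(c("accuracy", "sensitivity",
                                               "specificity", "auroc")),
                        names_to = "metric", values_to = "value")
  counts <- long |> dplyr::count(.data$level, .data$metric)
  if (any(counts$n != expected_n)) {
    warn(sprintf("expected %d records per level/metric, got %s",
                 expected_n, paste(unique(counts$n), collapse = ", ")))
  }
  if (anyNA(long$value)) {
    warn("dropping NA metric values before aggregation")
  }
  long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$level, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     median = median(.data$value), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(summary = sprintf("%.1f ± %.1f/%.1f",
                                    100 * .data$mean,
                                    100 * ifelse(is.na(.data$sd), 0, .data$sd),
                                    100 * .data$median))
}

significance_tier <- function(p) {
  dplyr::case_when(p < 0.001 ~ "p<0.001", p < 0.01 ~ "p<0.01",
                   TRUE ~ "ns")
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Paired Wilcoxon signed-rank comparison of two metric series
#'
#' Two-sided signed-rank test over paired cross-validation iterations
#' (zero differences dropped, exact distribution where \code{wilcox.test}
#' provides it).  Multiple-comparison caution is reflected in the
#' significance tier, which only distinguishes p < 0.01 and p < 0.001.
#'
#' @param a,b numeric vectors of paired per-iteration metric values (30 for
#'   the full protocol).
#' @param metric optional metric name carried into the result.
#' @return An object of class `rpe_comparison` with `statistic`, `p_value`,
#'   `tier` (`ns`, `p<0.01`, `p<0.001`) and `stars` (at 0.05/0.01/0.001).
#' @export
wilcoxon_compare <- function(a, b, metric = NULL) {
  if (length(a) != length(b)) abort("paired series must have equal length")
  d <- a - b
  if (all(d == 0)) {
    res <- list(statistic = NA_real_, p_value = 1)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
    res <- list(statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  structure(list(metric = metric %||% NA_character_,
                 a = a, b = b,
                 statistic = res$statistic, p_value = res$p_value,
                 tier = significance_tier(res$p_value),
                 stars = significance_stars(res$p_value),
                 n = length(a)),
            class = "rpe_comparison")
}

#' @export
print.rpe_comparison <- function(x, ...) {
  cat(sprintf(
    "<rpe_comparison>%s n = %d pairs, V = %s, p = %.4g (%s)\n",
    if (is.na(x$metric)) "" else paste0(" ", x$metric, ":"),
    x$n, format(x$statistic), x$p_value, x$tier))
  invisible(x)
}

#' @describeIn wilcoxon_compare one-row tibble of the test result.
#' @param x an `rpe_comparison`.
#' @param ... unused.
#' @export
tidy.rpe_comparison <- function(x, ...) {
  tibble(metric = x$metric, n = x$n, statistic = x$statistic,
         p_value = x$p_value, tier = x$tier, stars = x$stars,
         mean_a = mean(x$a), mean_b = mean(x$b))
}

#' @describeIn wilcoxon_compare alias of `tidy()` for a single test.
#' @export
glance.rpe_comparison <- function(x, ...) tidy(x)

#' Compare two runs metric-by-metric with paired Wilcoxon tests
#'
#' @param metrics_a,metrics_b per-iteration metric tibbles (as produced by
#'   [run_experiment()]), paired by `iteration_id` and `level`.
#' @return Tibble with one row per level/metric: test statistic, p-value,
#'   significance tier and stars, and the two means.
#' @export
compare_runs <- function(metrics_a, metrics_b) {
  to_long <- function(m, tag) {
    m |>
      tidyr::pivot_longer(dplyr::any_of(c("accuracy", "sensitivity",
                                          "specificity", "auroc")),
                          names_to = "metric", values_to = tag)
  }
  joined <- dplyr::inner_join(to_long(metrics_a, "value_a"),
                              to_long(metrics_b, "value_b"),
                              by = c("iteration_id", "level", "metric"))
  joined |>
    dplyr::group_by(.data$level, .data$metric) |>
    dplyr::group_modify(~ dplyr::select(
      tidy(wilcoxon_compare(.x$value_a, .x$value_b)), -"metric")) |>
    dplyr::ungroup()
}

pad_patient_vectors <- function(predictions, pad_length = NULL) {
  vecs <- predictions |>
    dplyr::arrange(.data$patient_id, .data$slice_index) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(scores = list(.data$score), .groups = "drop")
  lens <- lengths(vecs$scores)
  l_max <- max(lens)
  pad_length <- pad_length %||% l_max
  if (pad_length < l_max) {
    abort(sprintf("pad_length %d smaller than longest vector (%d)",
                  pad_length, l_max))
  }
  x <- matrix(0, nrow(vecs), pad_length)
  for (i in seq_len(nrow(vecs))) {
    x[i, seq_along(vecs$scores[[i]])] <- vecs$scores[[i]]
  }
  rownames(x) <- vecs$patient_id
  x
}

#' Padded-vector patient classifiers (random forest / SVM baselines)
#'
#' Each patient's ordered slice-score vector is right-padded with zeros to a
#' common length and fed to an off-the-shelf classifier (random forest or
#' support-vector machine).  Test scores are binarized at the threshold
#' maximizing Youden's index on the training-set scores.
#'
#' @param train_predictions,test_predictions prediction tibbles
#'   `(patient_id, slice_index, score)`.
#' @param train_patient_labels tibble `(patient_id, patient_label)` for the
#'   training patients.
#' @param kind `"random_forest"` or `"svm"`.
#' @param pad_length common padded length; defaults to the longest vector
#'   across both sets (errors if shorter than that).
#' @param seed seed for the classifier's internal randomness.
#' @param ... passed through to [randomForest::randomForest()] or
#'   [e1071::svm()].
#' @return Tibble `(patient_id, score, patient_label)` for the test
#'   patients, with the learned threshold in attribute `"threshold"`.
#' @export
baseline_patient_classifier <- function(train_predictions,
                                        train_patient_labels,
                                        test_predictions,
                                        kind = c("random_forest", "svm"),
                                        pad_length = NULL, seed = 1L, ...) {
  kind <- match.arg(kind)
  all_len <- max(dplyr::count(train_predictions, .data$patient_id)$n,
                 dplyr::count(test_predictions, .data$patient_id)$n)
  pad_length <- pad_length %||% all_len
  x_train <- pad_patient_vectors(train_predictions, pad_length)
  x_test <- pad_patient_vectors(test_predictions, pad_length)
  y <- train_patient_labels$patient_label[
    match(rownames(x_train), train_patient_labels$patient_id)]
  if (anyNA(y)) abort("patient labels missing for some training patients")

  if (kind == "random_forest") {
    fit <- with_seed(seed, randomForest::randomForest(
      x = x_train, y = factor(y, levels = c(0L, 1L)), ...))
    score_of <- function(x) unname(predict(fit, x, type = "prob")[, "1"])
    # out-of-bag votes give honest training scores for threshold selection
    # (refitting-set predictions are overfit to ~0/1)
    train_scores <- unname(fit$votes[, "1"])
  } else {
    # linear kernel: the padded score vector is built for a linear margin,
    # and a radial kernel at these sample sizes makes every training point
    # a margin vector (decision values pinned to +/-1), leaving the
    # training-set Youden threshold nowhere to generalize
    fit <- with_seed(seed, e1071::svm(
      x = x_train, y = factor(y, levels = c(0L, 1L)), kernel = "linear",
      ...))
    score_of <- function(x) {
      dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
      s <- dv[, 1]
      # orient decision values so that larger means class "1"
      if (grepl("^0/1$", colnames(dv)[1])) s <- -s
      unname(s)
    }
    train_scores <- score_of(x_train)
  }
  threshold <- select_threshold_max_youden(train_scores, y)
  test_scores <- score_of(x_test)
  out <- tibble(patient_id = rownames(x_test), score = test_scores,
                patient_label = as.integer(test_scores >= threshold))
  attr(out, "threshold") <- threshold
  attr(out, "kind") <- kind
  out
}
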