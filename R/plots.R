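#' @export
ggplot2::autoplot

#' Plot per-iteration metrics of an experiment
#'
#' Boxplots of the four evaluation metrics over the cross-validation
#' iterations, split by evaluation level.
#'
#' @param object an `rpe_experiment`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rpe_experiment <- function(object, ...) {
  long <- object$metrics |>
    tidyr::pivot_longer(dplyr::any_of(c("accuracy", "sensitivity",
                                        "specificity", "auroc")),
                        names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$metric, y = .data$value,
                   fill = .data$level)) +
    geom_boxplot(outlier.size = 0.8, position = position_dodge(0.8)) +
    scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    labs(x = NULL, y = NULL, fill = "level",
         title = "Evaluation metrics across CV iterations") +
    theme_minimal()
}

#' Plot the training history of a slice classifier
#'
#' @param object a trained `rpe_cnn`.
#' @param ... unused.
#' @return A ggplot object with training and validation loss per epoch.
#' @export
autoplot.rpe_cnn <- function(object, ...) {
  if (is.null(object$history)) abort("model has no training history yet")
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                              names_to = "series", values_to = "loss")
  ggplot(long, aes(x = .data$epoch, y = .data$loss,
                   colour = .data$series)) +
    geom_line() +
    geom_point(size = 1) +
    geom_vline(xintercept = object$best_epoch, linetype = "dashed",
               colour = "grey50") +
    labs(title = "Training history (dashed: restored epoch)",
         x = "epoch", y = "binary cross-entropy") +
    theme_minimal()
}

#' ROC curve of a score vector
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param title plot title.
#' @return A ggplot object; the AUROC appears in the subtitle.
#' @export
plot_roc <- function(scores, labels, title = "ROC curve") {
  r <- pROC::roc(response = as.integer(labels), predictor = scores,
                 levels = c(0L, 1L), direction = "<", quiet = TRUE)
  d <- tibble(fpr = 1 - r$specificities, tpr = r$sensitivities) |>
    dplyr::arrange(.data$fpr, .data$tpr)
  ggplot(d, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    coord_equal() +
    labs(title = title,
         subtitle = sprintf("AUROC = %.3f", as.numeric(pROC::auc(r))),
         x = "1 - specificity", y = "sensitivity") +
    theme_minimal()
}

#' Plot one patient's slice-score profile
#'
#' Raw slice scores along the stack with the windowed means, the patient
#' threshold and (when supplied) the annotated positive range.
#'
#' @param predictions prediction tibble for one patient.
#' @param thresholds optional `rpe_thresholds` drawn as horizontal lines.
#' @param annotation optional one-row annotation tibble; its positive range
#'   is shaded.
#' @return A ggplot object.
#' @export
plot_patient_profile <- function(predictions, thresholds = NULL,
                                 annotation = NULL) {
  stopifnot(length(unique(predictions$patient_id)) == 1L)
  d <- dplyr::arrange(predictions, .data$slice_index)
  w <- if (is.null(thresholds)) 5L else thresholds$window
  wm <- tibble(
    slice_index = d$slice_index[seq_len(nrow(d) - w + 1L)] + (w - 1) / 2,
    value = windowed_mean_scores(d$score, w))
  p <- ggplot(d, aes(x = .data$slice_index, y = .data$score)) +
    geom_line(colour = "grey60") +
    geom_point(size = 1) +
    geom_line(data = wm, aes(y = .data$value), colour = "steelblue") +
    labs(title = sprintf("Patient %s", d$patient_id[1]),
         x = "slice index", y = "score") +
    theme_minimal()
  if (!is.null(thresholds)) {
    p <- p + geom_hline(yintercept = thresholds$theta_patient,
                        linetype = "dashed", colour = "steelblue") +
      geom_hline(yintercept = thresholds$theta_slice,
                 linetype = "dotted", colour = "darkred")
  }
  if (!is.null(annotation) && annotation$patient_label[1] == 1L) {
    p <- p + annotate("rect", xmin = annotation$uppermost_idx[1] - 0.5,
                      xmax = annotation$lowermost_idx[1] + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.12,
                      fill = "darkred")
  }
  p
}
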