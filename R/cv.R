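#' Patient-wise fold assignments for repeated five-fold cross-validation
#'
#' The patients are partitioned once into `n_folds` near-equal folds (sizes
#' differ by at most one patient); the same folds are then reused across the
#' `n_reps` repetitions, so the protocol yields `n_folds * n_reps`
#' iterations.  Within each iteration a fresh random 30% of the training
#' patients is set aside as the validation set (drawn patient-wise so no
#' patient straddles partitions); the remaining training patients carry the
#' `train` role.
#'
#' @param patient_ids character vector of patient identifiers.
#' @param n_folds number of folds (default 5).
#' @param n_reps number of repetitions of the fold cycle (default 6).
#' @param seed integer seed for the fold draw and the validation draws.
#' @param validation_fraction fraction of training patients assigned to
#'   validation in each iteration (default 0.3).
#' @return Tibble with one row per patient per iteration: `iteration_id`,
#'   `repetition_id`, `fold_id`, `patient_id`, `role` (`train`,
#'   `validation` or `test`).
#' @export
make_folds <- function(patient_ids, n_folds = 5L, n_reps = 6L, seed = 1L,
                       validation_fraction = 0.3) {
  patient_ids <- as.character(patient_ids)
  n <- length(patient_ids)
  if (n < n_folds) abort(sprintf("need at least %d patients, got %d",
                                 n_folds, n))
  fold_sizes <- rep(n %/% n_folds, n_folds) +
    c(rep(1L, n %% n_folds), rep(0L, n_folds - n %% n_folds))
  fold_of <- with_seed(derive_seed(seed, "folds"), {
    shuffled <- sample(patient_ids)
    stats::setNames(rep(seq_len(n_folds), times = fold_sizes),
                    shuffled)[patient_ids]
  })
  out <- vector("list", n_folds * n_reps)
  for (rep_id in seq_len(n_reps)) {
    for (fold_id in seq_len(n_folds)) {
      it <- (rep_id - 1L) * n_folds + fold_id
      role <- ifelse(fold_of == fold_id, "test", "train")
      train_ids <- patient_ids[role == "train"]
      n_val <- round(validation_fraction * length(train_ids))
      val_ids <- with_seed(derive_seed(seed, "validation", it),
                           sample(train_ids, n_val))
      role[patient_ids %in% val_ids] <- "validation"
      out[[it]] <- tibble(iteration_id = it, repetition_id = rep_id,
                          fold_id = fold_id, patient_id = patient_ids,
                          role = role)
    }
  }
  dplyr::bind_rows(out)
}

bind_patient_slices <- function(dataset, ids) {
  if (length(ids) == 0L) {
    return(list(x = array(0, c(1L, 1L, 0L)), labels = integer(),
                patient_id = character()))
  }
  arrays <- dataset$x[ids]
  ns <- vapply(arrays, function(a) dim(a)[3], integer(1))
  side <- dim(arrays[[1]])[1]
  x <- array(0, c(side, side, sum(ns)))
  at <- 0L
  for (a in arrays) {
    x[, , at + seq_len(dim(a)[3])] <- a
    at <- at + dim(a)[3]
  }
  lab <- dataset$slice_labels |>
    dplyr::filter(.data$patient_id %in% ids) |>
    dplyr::arrange(match(.data$patient_id, ids), .data$slice_index)
  list(x = x, labels = lab$label, patient_id = lab$patient_id)
}

predict_patients <- function(model, dataset, ids) {
  purrr::map_dfr(ids, function(id) {
    predict_slices(model, dataset$x[[id]], patient_id = id)
  })
}

#' Run one cross-validation iteration of the full pipeline
#'
#' Standardized slices of the training patients are augmented, a freshly
#' initialized classifier is trained with early stopping on the validation
#' patients, thresholds are fitted on the training patients' predictions
#' only, and the held-out test patients are classified and finalized.
#' Nothing derived from a test patient ever reaches training, augmentation
#' or threshold fitting.
#'
#' @param dataset an `rpe_dataset` (see [generate_dataset()] /
#'   [preprocess_cohort()]).
#' @param folds fold-assignment tibble from [make_folds()].
#' @param iteration iteration id to run.
#' @param network a [network_config()].
#' @param training a [training_config()] (its `seed` drives data order).
#' @param augmentation one of [augmentation_kinds()] (training set only).
#' @param window window length of the patient score.
#' @param init_seed seed for the fresh weight initialization.
#' @return List with `metrics` (two-row tibble: slice and patient level),
#'   `thresholds`, `predictions` (test slices with `final_label`),
#'   `patient_results`, `model` and `timing_s`.
#' @export
run_iteration <- function(dataset, folds, iteration,
                          network = network_config(),
                          training = training_config(),
                          augmentation = "reflect_vertical",
                          window = 5L, init_seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  roles <- dplyr::filter(folds, .data$iteration_id == iteration)
  if (nrow(roles) == 0L) abort(sprintf("no fold assignment for iteration %d",
                                       iteration))
  ids_of <- function(r) roles$patient_id[roles$role == r]
  train_ids <- ids_of("train")
  val_ids <- ids_of("validation")
  test_ids <- ids_of("test")

  train <- bind_patient_slices(dataset, train_ids)
  val <- bind_patient_slices(dataset, val_ids)
  aug <- augment_training_set(train$x, train$labels, augmentation)

  model <- build_model(network, seed = init_seed)
  model <- train_model(model, aug$slices, aug$labels, val$x, val$labels,
                       training)

  train_preds <- predict_patients(model, dataset, train_ids)
  test_preds <- predict_patients(model, dataset, test_ids)

  ann <- dataset$annotations
  patient_truth <- ann[, c("patient_id", "patient_label")]
  thresholds <- fit_thresholds(
    train_preds,
    dplyr::semi_join(dataset$slice_labels, tibble(patient_id = train_ids),
                     by = "patient_id"),
    dplyr::semi_join(patient_truth, tibble(patient_id = train_ids),
                     by = "patient_id"),
    window)

  patient_results <- classify_patients(test_preds, thresholds)
  test_final <- finalize_slice_labels(test_preds, thresholds,
                                      patient_results)

  slice_truth <- dplyr::inner_join(
    test_final, dataset$slice_labels, by = c("patient_id", "slice_index"))
  patient_eval <- dplyr::inner_join(patient_results, patient_truth,
                                    by = "patient_id")

  safe_auc <- function(expr) {
    tryCatch(expr, error = function(e) {
      warn(paste("AUROC undefined:", conditionMessage(e)))
      NA_real_
    })
  }

  slice_cm <- confusion_metrics(slice_truth$final_label, slice_truth$label)
  patient_cm <- confusion_metrics(patient_eval$patient_label.x,
                                  patient_eval$patient_label.y)
  metrics <- dplyr::bind_rows(
    tibble(level = "slice",
           accuracy = slice_cm$accuracy, sensitivity = slice_cm$sensitivity,
           specificity = slice_cm$specificity,
           auroc = safe_auc(roc_auc(slice_truth$score, slice_truth$label))),
    tibble(level = "patient",
           accuracy = patient_cm$accuracy,
           sensitivity = patient_cm$sensitivity,
           specificity = patient_cm$specificity,
           auroc = safe_auc(patient_roc_auc(
             test_preds,
             dplyr::semi_join(patient_truth, tibble(patient_id = test_ids),
                              by = "patient_id"),
             window))))

  list(metrics = metrics, thresholds = thresholds,
       predictions = test_final, patient_results = patient_results,
       model = model, timing_s = proc.time()[["elapsed"]] - t0)
}

#' Run a repeated cross-validation experiment
#'
#' Executes `n_folds * n_reps` iterations of [run_iteration()] (30 under the
#' default protocol) with a freshly initialized classifier per iteration,
#' and aggregates the per-iteration metrics into a "mean ± SD/median"
#' summary.  With `out_dir`, per-iteration artifacts (metrics TSV,
#' thresholds JSON, test predictions TSV) are written and previously
#' completed iterations are resumed rather than recomputed.
#'
#' @param dataset an `rpe_dataset`.
#' @param n_folds,n_reps protocol dimensions (5 x 6 by default).
#' @param network,training,augmentation,window forwarded to
#'   [run_iteration()]; per-iteration data-order and initialization seeds
#'   are derived from `seed`.
#' @param seed master seed for folds, initialization and shuffling.
#' @param iterations optional subset of iteration ids to run.
#' @param out_dir optional artifact directory.
#' @param verbose print per-iteration progress?
#' @return An object of class `rpe_experiment` with `metrics` (one row per
#'   iteration and level), `summary`, `folds` and the configuration.
#' @export
run_experiment <- function(dataset, n_folds = 5L, n_reps = 6L,
                           network = network_config(),
                           training = training_config(),
                           augmentation = "reflect_vertical",
                           window = 5L, seed = 1L, iterations = NULL,
                           out_dir = NULL, verbose = FALSE) {
  folds <- make_folds(dataset$annotations$patient_id, n_folds, n_reps, seed)
  iterations <- iterations %||% seq_len(n_folds * n_reps)
  metric_rows <- vector("list", length(iterations))
  for (j in seq_along(iterations)) {
    it <- iterations[j]
    it_dir <- if (!is.null(out_dir)) {
      file.path(out_dir, sprintf("iteration_%02d", it))
    }
    metrics_path <- if (!is.null(it_dir)) file.path(it_dir, "metrics.tsv")
    if (!is.null(metrics_path) && file.exists(metrics_path)) {
      metric_rows[[j]] <- as_tibble(read.delim(metrics_path))
      next
    }
    it_training <- training
    it_training$seed <- derive_seed(seed, "train", it)
    res <- run_iteration(dataset, folds, it, network, it_training,
                         augmentation, window,
                         init_seed = derive_seed(seed, "init", it))
    row <- dplyr::mutate(res$metrics, iteration_id = it,
                         repetition_id = (it - 1L) %/% n_folds + 1L,
                         fold_id = (it - 1L) %% n_folds + 1L,
                         timing_s = res$timing_s, .before = 1)
    if (!is.null(it_dir)) {
      dir.create(it_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(row, metrics_path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      save_thresholds(res$thresholds, file.path(it_dir, "thresholds.json"))
      write_predictions(res$predictions, file.path(it_dir, "predictions.tsv"))
    }
    metric_rows[[j]] <- row
    if (verbose) {
      message(sprintf("iteration %d/%d done in %.1f s", it,
                      n_folds * n_reps, res$timing_s))
    }
  }
  metrics <- dplyr::bind_rows(metric_rows)
  expected <- n_folds * n_reps
  missing_its <- setdiff(iterations, metrics$iteration_id)
  if (length(missing_its) > 0) {
    warn(sprintf("missing iteration(s): %s",
                 paste(missing_its, collapse = ", ")))
  }
  summary <- suppressWarnings(
    aggregate_iterations(metrics, expected_n = expected))
  structure(list(metrics = metrics, summary = summary, folds = folds,
                 n_folds = n_folds, n_reps = n_reps, network = network,
                 training = training, augmentation = augmentation,
                 window = window, seed = seed),
            class = "rpe_experiment")
}

#' @export
print.rpe_experiment <- function(x, ...) {
  cat(sprintf(
    "<rpe_experiment> %d iteration(s) of %d-fold x %d-rep patient-wise CV (augmentation: %s)\n",
    length(unique(x$metrics$iteration_id)), x$n_folds, x$n_reps,
    x$augmentation))
  s <- x$summary
  for (lv in unique(s$level)) {
    cat(sprintf("  %s level: %s\n", lv,
                paste(sprintf("%s %s", s$metric[s$level == lv],
                              s$summary[s$level == lv]), collapse = ", ")))
  }
  invisible(x)
}

#' @describeIn run_experiment per-iteration metrics as a tibble.
#' @param x an `rpe_experiment`.
#' @param ... unused.
#' @export
tidy.rpe_experiment <- function(x, ...) x$metrics

#' @describeIn run_experiment the "mean ± SD/median" summary tibble.
#' @export
glance.rpe_experiment <- function(x, ...) x$summary
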