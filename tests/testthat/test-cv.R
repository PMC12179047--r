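test_that("patient-wise folds partition a full-scale cohort", {
  ids <- sprintf("P%03d", 1:479)
  folds <- make_folds(ids, n_folds = 5, n_reps = 6, seed = 2)
  expect_equal(nrow(folds), 479 * 30)
  expect_equal(sort(unique(folds$iteration_id)), 1:30)

  # fold sizes 95/96/96/96/96
  sizes <- folds |>
    dplyr::filter(repetition_id == 1, role == "test") |>
    dplyr::count(fold_id)
  expect_setequal(sizes$n, c(95, 96))
  expect_equal(sum(sizes$n), 479)

  # every patient is test exactly once per repetition, 6 times overall
  test_counts <- folds |>
    dplyr::filter(role == "test") |>
    dplyr::count(patient_id)
  expect_true(all(test_counts$n == 6))

  # roles partition the cohort in every iteration; train/test disjoint
  by_it <- split(folds, folds$iteration_id)
  for (it in by_it[c(1, 15, 30)]) {
    expect_setequal(it$patient_id, ids)
    expect_length(intersect(it$patient_id[it$role != "test"],
                            it$patient_id[it$role == "test"]), 0)
    # validation is 30% of the training patients
    n_test <- sum(it$role == "test")
    expect_equal(sum(it$role == "validation"),
                 round(0.3 * (479 - n_test)))
  }

  # the five folds are drawn once and reused across repetitions
  test_sets <- folds |>
    dplyr::filter(role == "test") |>
    dplyr::group_by(repetition_id, fold_id) |>
    dplyr::summarise(ids = paste(sort(patient_id), collapse = ","),
                     .groups = "drop")
  per_fold <- split(test_sets$ids, test_sets$fold_id)
  for (f in per_fold) expect_length(unique(f), 1)

  # but validation draws are fresh per iteration
  val_sets <- folds |>
    dplyr::filter(role == "validation") |>
    dplyr::group_by(iteration_id) |>
    dplyr::summarise(ids = paste(sort(patient_id), collapse = ","),
                     .groups = "drop")
  expect_gt(length(unique(val_sets$ids)), 1)

  expect_error(make_folds(c("a", "b"), n_folds = 5), "at least 5")
})

test_that("fold assignments are seed-deterministic", {
  ids <- sprintf("P%02d", 1:23)
  expect_identical(make_folds(ids, seed = 7), make_folds(ids, seed = 7))
  expect_false(identical(make_folds(ids, seed = 7),
                         make_folds(ids, seed = 8)))
})

test_that("one iteration runs the full pipeline deterministically", {
  ds <- tiny_dataset(n_patients = 12L, seed = 7L)
  folds <- make_folds(ds$annotations$patient_id, n_folds = 3, n_reps = 1,
                      seed = 2)
  run <- function() {
    suppressWarnings(run_iteration(
      ds, folds, 1, training = fast_training(), init_seed = 11))
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$model$weights, r2$model$weights)
  expect_identical(r1$thresholds$theta_patient, r2$thresholds$theta_patient)

  # output structure
  expect_equal(r1$metrics$level, c("slice", "patient"))
  test_ids <- folds$patient_id[folds$iteration_id == 1 &
                                 folds$role == "test"]
  expect_setequal(unique(r1$predictions$patient_id), test_ids)
  expect_true(all(c("score", "final_label") %in% names(r1$predictions)))
})

test_that("test patients cannot leak into training or thresholds", {
  ds <- tiny_dataset(n_patients = 12L, seed = 7L)
  folds <- make_folds(ds$annotations$patient_id, n_folds = 3, n_reps = 1,
                      seed = 2)
  test_ids <- folds$patient_id[folds$iteration_id == 1 &
                                 folds$role == "test"]
  poisoned <- ds
  for (id in test_ids) {
    poisoned$x[[id]] <- array(withr::with_seed(99, runif(length(ds$x[[id]]))),
                              dim(ds$x[[id]]))
  }
  r_clean <- suppressWarnings(run_iteration(ds, folds, 1,
                                            training = fast_training(),
                                            init_seed = 11))
  r_poison <- suppressWarnings(run_iteration(poisoned, folds, 1,
                                             training = fast_training(),
                                             init_seed = 11))
  # poisoning the held-out pixels changes neither the trained weights nor
  # the thresholds fitted on training predictions
  expect_identical(r_clean$model$weights, r_poison$model$weights)
  expect_identical(r_clean$thresholds$theta_patient,
                   r_poison$thresholds$theta_patient)
  expect_identical(r_clean$thresholds$theta_slice,
                   r_poison$thresholds$theta_slice)
  # while the test predictions do change
  expect_false(identical(r_clean$predictions$score,
                         r_poison$predictions$score))
})

test_that("models are re-initialized freshly every iteration", {
  ds <- tiny_dataset(n_patients = 9L, seed = 4L)
  folds <- make_folds(ds$annotations$patient_id, n_folds = 3, n_reps = 1,
                      seed = 3)
  r1 <- suppressWarnings(run_iteration(ds, folds, 1,
                                       training = fast_training(max_epochs = 1),
                                       init_seed = 21))
  r2 <- suppressWarnings(run_iteration(ds, folds, 2,
                                       training = fast_training(max_epochs = 1),
                                       init_seed = 22))
  r1b <- suppressWarnings(run_iteration(ds, folds, 1,
                                        training = fast_training(max_epochs = 1),
                                        init_seed = 21))
  expect_false(identical(r1$model$weights, r2$model$weights))
  expect_identical(r1$model$weights, r1b$model$weights)
})

test_that("experiments aggregate iterations and resume from artifacts", {
  ds <- tiny_dataset(n_patients = 9L, seed = 4L)
  out_dir <- withr::local_tempdir()
  ex <- suppressWarnings(run_experiment(
    ds, n_folds = 3, n_reps = 1, training = fast_training(max_epochs = 1),
    seed = 6, out_dir = out_dir))
  expect_s3_class(ex, "rpe_experiment")
  expect_equal(nrow(ex$metrics), 6)  # 3 iterations x 2 levels
  expect_true(all(c("level", "metric", "summary") %in% names(ex$summary)))
  expect_true(file.exists(file.path(out_dir, "iteration_01",
                                    "thresholds.json")))
  expect_true(file.exists(file.path(out_dir, "iteration_02",
                                    "predictions.tsv")))

  # resume: artifacts short-circuit recomputation bit-identically
  ex2 <- suppressWarnings(run_experiment(
    ds, n_folds = 3, n_reps = 1, training = fast_training(max_epochs = 1),
    seed = 6, out_dir = out_dir))
  expect_equal(ex2$metrics$accuracy, ex$metrics$accuracy, tolerance = 1e-12)

  # tidy/glance accessors
  expect_identical(tidy(ex), ex$metrics)
  expect_identical(glance(ex), ex$summary)
})

test_that("plots build without evaluation", {
  ds <- tiny_dataset(n_patients = 9L, seed = 4L)
  folds <- make_folds(ds$annotations$patient_id, n_folds = 3, n_reps = 1,
                      seed = 3)
  r <- suppressWarnings(run_iteration(ds, folds, 1,
                                      training = fast_training(max_epochs = 2),
                                      init_seed = 1))
  p1 <- autoplot(r$model)
  expect_s3_class(p1, "ggplot")
  one <- r$predictions[r$predictions$patient_id ==
                         r$predictions$patient_id[1], ]
  p2 <- plot_patient_profile(one, r$thresholds)
  expect_s3_class(p2, "ggplot")
  p3 <- plot_roc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_s3_class(p3, "ggplot")
})
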