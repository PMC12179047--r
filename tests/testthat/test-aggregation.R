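test_that("windowed means enumerate consecutive windows in order", {
  expect_equal(windowed_mean_scores(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)),
               c(0.3, 0.4))
  # n - W + 1 windows: a constant length-10 vector has 6 of them
  expect_equal(windowed_mean_scores(rep(0.7, 10)), rep(0.7, 6))
  expect_error(windowed_mean_scores(c(0.1, 0.2, 0.3, 0.4)), "at least 5")
})

test_that("the patient score matches brute-force window enumeration", {
  expect_equal(patient_score(c(0, 0, 1, 1, 1, 1, 1, 0, 0)), 1.0)
  expect_equal(patient_score(rep(0, 10)), 0.0)
  expect_equal(patient_score(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)), 0.4)

  withr::with_seed(42, {
    for (i in 1:1000) {
      v <- runif(sample(5:60, 1))
      expect_equal(patient_score(v), oracle_window_max(v))
    }
  })
})

test_that("patient scores are bounded and monotone in the slice scores", {
  withr::with_seed(7, {
    for (i in 1:200) {
      v <- runif(sample(5:40, 1))
      s <- patient_score(v)
      expect_gte(s, min(v))
      expect_lte(s, max(v))
      bump <- pmin(1, v + runif(length(v), 0, 0.3))
      expect_gte(patient_score(bump), s)
    }
  })
})

test_that("Youden's index is sensitivity + specificity - 1", {
  expect_equal(youden_index(1, 1), 1)
  expect_equal(youden_index(0.5, 0.5), 0)
  expect_equal(youden_index(0.833, 0.962), 0.795)
  expect_error(youden_index(1.2, 0.5), "\\[0, 1\\]")
})

test_that("threshold selection agrees with the exhaustive sweep oracle", {
  expect_equal(select_threshold_max_youden(c(0.1, 0.2, 0.8, 0.9),
                                           c(0, 0, 1, 1)), 0.8)

  withr::with_seed(11, {
    for (i in 1:300) {
      n <- sample(4:50, 1)
      labels <- sample(c(0L, 1L), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      # mix continuous and heavily tied discrete scores
      scores <- if (i %% 2 == 0) runif(n) else sample(seq(0, 1, 0.1), n,
                                                      replace = TRUE)
      got <- suppressWarnings(select_threshold_max_youden(scores, labels))
      oracle <- oracle_youden_threshold(scores, labels)
      j_got <- {
        pred <- as.integer(scores >= got)
        sum(pred & labels) / sum(labels) +
          sum(!pred & !labels) / sum(!labels) - 1
      }
      expect_equal(j_got, oracle$j)
      # same decisions as the oracle's (largest-threshold tie rule)
      expect_equal(as.integer(scores >= got),
                   as.integer(scores >= oracle$threshold))
    }
  })
})

test_that("degenerate threshold inputs warn or error", {
  expect_warning(th <- select_threshold_max_youden(rep(0.4, 6),
                                                   c(0, 1, 0, 1, 0, 1)),
                 "max Youden")
  # J = 0 at the degenerate candidate; largest-threshold tie rule picks the
  # all-negative sentinel
  expect_gt(th, 0.4)
  expect_error(select_threshold_max_youden(c(0.2, 0.8), c(1, 1)),
               "both classes")
})

test_that("patients classify by thresholded window maximum, ties positive", {
  preds <- tibble::tibble(
    patient_id = rep(c("hi", "lo", "tie"), each = 6),
    slice_index = rep(0:5, 3),
    score = c(rep(0.9, 6), rep(0.2, 6), rep(0.5, 6)))
  out <- classify_patients(preds, 0.5)
  expect_equal(out$patient_label[out$patient_id == "hi"], 1L)
  expect_equal(out$patient_label[out$patient_id == "lo"], 0L)
  expect_equal(out$patient_label[out$patient_id == "tie"], 1L)
})

test_that("negative patients override every slice label", {
  preds <- tibble::tibble(patient_id = rep(c("neg", "pos"), c(5, 5)),
                          slice_index = rep(0:4, 2),
                          score = c(rep(0.9, 5), 0.9, 0.1, 0.6, 0.2, 0.55))
  labels <- tibble::tibble(patient_id = c("neg", "pos"),
                           patient_label = c(0L, 1L))
  thresholds <- structure(list(theta_patient = 0.95, theta_slice = 0.5,
                               window = 5L), class = "rpe_thresholds")
  out <- finalize_slice_labels(preds, thresholds, labels)
  expect_equal(out$final_label[out$patient_id == "neg"], rep(0L, 5))
  expect_equal(out$final_label[out$patient_id == "pos"],
               c(1L, 0L, 1L, 0L, 1L))

  # positive patient whose every score is under the slice threshold
  low <- tibble::tibble(patient_id = "pos", slice_index = 0:4,
                        score = rep(0.3, 5))
  out2 <- finalize_slice_labels(low, thresholds,
                                tibble::tibble(patient_id = "pos",
                                               patient_label = 1L))
  expect_equal(out2$final_label, rep(0L, 5))

  # property: on random cohorts, predicted-negative patients have only
  # negative finalized slices
  preds_r <- random_predictions(20, seed = 3)
  ths <- structure(list(theta_patient = 0.6, theta_slice = 0.5, window = 5L),
                   class = "rpe_thresholds")
  fin <- finalize_slice_labels(preds_r, ths)
  cls <- classify_patients(preds_r, ths)
  neg_ids <- cls$patient_id[cls$patient_label == 0L]
  expect_true(all(fin$final_label[fin$patient_id %in% neg_ids] == 0L))
})

test_that("fitted thresholds reproduce the exhaustive oracle on a toy cohort", {
  # 6 hand-built score vectors, 3 clearly positive
  preds <- dplyr::bind_rows(
    tibble::tibble(patient_id = "A", slice_index = 0:7,
                   score = c(.1, .2, .9, .95, .9, .85, .2, .1)),
    tibble::tibble(patient_id = "B", slice_index = 0:6,
                   score = c(.2, .7, .8, .9, .75, .8, .3)),
    tibble::tibble(patient_id = "C", slice_index = 0:5,
                   score = c(.6, .7, .65, .8, .75, .6)),
    tibble::tibble(patient_id = "D", slice_index = 0:7,
                   score = c(.1, .15, .2, .1, .05, .1, .2, .15)),
    tibble::tibble(patient_id = "E", slice_index = 0:5,
                   score = c(.3, .2, .25, .3, .35, .2)),
    tibble::tibble(patient_id = "F", slice_index = 0:6,
                   score = c(.05, .1, .4, .45, .3, .2, .1)))
  plabels <- tibble::tibble(patient_id = LETTERS[1:6],
                            patient_label = c(1L, 1L, 1L, 0L, 0L, 0L))
  slabels <- preds |>
    dplyr::mutate(label = as.integer(score >= 0.6)) |>
    dplyr::select(patient_id, slice_index, label)

  fit <- fit_thresholds(preds, slabels, plabels)
  ps <- patient_scores(preds)
  oracle_p <- oracle_youden_threshold(
    ps$patient_score, plabels$patient_label[match(ps$patient_id,
                                                  plabels$patient_id)])
  joined <- dplyr::inner_join(preds, slabels,
                              by = c("patient_id", "slice_index"))
  oracle_s <- oracle_youden_threshold(joined$score, joined$label)
  expect_equal(as.integer(ps$patient_score >= fit$theta_patient),
               as.integer(ps$patient_score >= oracle_p$threshold))
  expect_equal(as.integer(joined$score >= fit$theta_slice),
               as.integer(joined$score >= oracle_s$threshold))

  # perfectly separated cohort: both thresholds reach J = 1
  expect_equal(oracle_p$j, 1)
  td <- tidy(fit)
  expect_equal(td$level, c("patient", "slice"))
})

test_that("thresholds serialize through JSON unchanged", {
  th <- structure(list(theta_patient = 1 / 3, theta_slice = 0.123456789,
                       window = 5L, n_train_patients = 6L,
                       n_train_slices = 40L), class = "rpe_thresholds")
  path <- withr::local_tempfile(fileext = ".json")
  save_thresholds(th, path)
  back <- load_thresholds(path)
  expect_equal(back$theta_patient, th$theta_patient)
  expect_equal(back$theta_slice, th$theta_slice)
  expect_equal(back$window, th$window)
})
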