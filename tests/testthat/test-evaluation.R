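test_that("confusion metrics follow their definitions", {
  # tp=3, fp=1, tn=5, fn=1
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  truth <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- confusion_metrics(pred, truth)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(3, 1, 5, 1))

  perfect <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(perfect[, 1:3]), c(accuracy = 1, sensitivity = 1,
                                         specificity = 1))

  expect_warning(none <- confusion_metrics(c(0, 0), c(0, 0)),
                 "sensitivity undefined")
  expect_true(is.na(none$sensitivity))
  expect_error(confusion_metrics(1, c(1, 0)), "length mismatch")
  expect_error(confusion_metrics(integer(), integer()), "empty")
})

test_that("AUROC equals the pairwise Mann-Whitney probability", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")

  withr::with_seed(5, {
    for (i in 1:200) {
      n <- sample(6:40, 1)
      labels <- sample(c(0L, 1L), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- if (i %% 2 == 0) rnorm(n) else sample(1:5, n, replace = TRUE)
      expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
    }
  })
})

test_that("AUROC is monotone-invariant and complements under negation", {
  withr::with_seed(8, {
    scores <- rnorm(50)
    labels <- sample(c(0L, 1L), 50, replace = TRUE)
    a <- roc_auc(scores, labels)
    expect_equal(roc_auc(exp(scores), labels), a)
    expect_equal(roc_auc(rank(scores), labels), a)
    expect_equal(roc_auc(-scores, labels), 1 - a)  # tie-free scores
  })
})

test_that("null scores give chance-level AUROC at large n", {
  withr::with_seed(2, {
    scores <- runif(4000)
    labels <- sample(c(0L, 1L), 4000, replace = TRUE)
    expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.05)
  })
})

test_that("patient-level AUROC composes the window and ROC oracles", {
  preds <- dplyr::bind_rows(
    tibble::tibble(patient_id = "A", slice_index = 0:6,
                   score = c(0, 0, 0.9, 0.9, 0.9, 0.9, 0.9)),
    tibble::tibble(patient_id = "B", slice_index = 0:5,
                   score = c(0.4, 0.5, 0.45, 0.5, 0.4, 0.45)),
    tibble::tibble(patient_id = "C", slice_index = 0:5,
                   score = rep(0.2, 6)),
    tibble::tibble(patient_id = "D", slice_index = 0:7,
                   score = c(0.3, 0.6, 0.7, 0.6, 0.65, 0.6, 0.3, 0.2)))
  labels <- tibble::tibble(patient_id = LETTERS[1:4],
                           patient_label = c(1L, 0L, 0L, 1L))
  maxima <- vapply(LETTERS[1:4], function(id) {
    oracle_window_max(preds$score[preds$patient_id == id])
  }, numeric(1))
  expect_equal(patient_roc_auc(preds, labels),
               oracle_auc(maxima, labels$patient_label))

  # perfectly separated patients
  sep <- dplyr::bind_rows(
    tibble::tibble(patient_id = "P", slice_index = 0:5, score = rep(1, 6)),
    tibble::tibble(patient_id = "N", slice_index = 0:5, score = rep(0, 6)))
  expect_equal(patient_roc_auc(sep, tibble::tibble(
    patient_id = c("P", "N"), patient_label = c(1L, 0L))), 1)

  # all-equal patient scores fall back to the tie convention
  tied <- dplyr::mutate(sep, score = 0.5)
  expect_equal(patient_roc_auc(tied, tibble::tibble(
    patient_id = c("P", "N"), patient_label = c(1L, 0L))), 0.5)
})

test_that("iteration summaries report mean, SD and median", {
  base <- tidyr::expand_grid(iteration_id = 1:30,
                             level = c("slice", "patient"))
  same <- dplyr::mutate(base, accuracy = 0.9, sensitivity = 0.8,
                        specificity = 0.85, auroc = 0.95)
  s <- aggregate_iterations(same)
  expect_true(all(s$sd == 0))
  expect_equal(s$mean[s$level == "slice" & s$metric == "accuracy"], 0.9)
  expect_match(s$summary[s$metric == "auroc"][1], "95.0 ± 0.0/95.0")

  ramp <- dplyr::mutate(base, accuracy = iteration_id / 30,
                        sensitivity = 0.5, specificity = 0.5, auroc = 0.5)
  s2 <- aggregate_iterations(ramp)
  expect_equal(s2$mean[s2$metric == "accuracy"][1], mean(1:30) / 30)
  expect_equal(s2$median[s2$metric == "accuracy"][1], 15.5 / 30)

  # degraded mode: one missing record warns and aggregates the other 29
  holey <- same
  holey$accuracy[holey$level == "slice"][1] <- NA
  expect_warning(s3 <- aggregate_iterations(holey), "NA")
  expect_equal(s3$n[s3$metric == "accuracy" & s3$level == "slice"], 29)
  expect_true(all(s3$mean >= 0 & s3$mean <= 1))
  expect_warning(aggregate_iterations(same[1:10, ]), "expected 30")
})

test_that("paired Wilcoxon comparisons match exact enumeration", {
  expect_equal(wilcoxon_compare(1:30 / 30, 1:30 / 30)$tier, "ns")
  expect_equal(wilcoxon_compare(1:30 / 30, 1:30 / 30)$p_value, 1)

  # constant shift b = a + 1: every sign positive, p far below 0.001
  a <- withr::with_seed(1, runif(30))
  shifted <- wilcoxon_compare(a + 1, a)
  expect_lt(shifted$p_value, 0.001)
  expect_equal(shifted$tier, "p<0.001")
  # with distinct absolute differences the exact null applies:
  # all 30 signs positive gives two-sided p = 2 * 2^-30
  jitter <- withr::with_seed(2, runif(30, 0.5, 1.5))
  exact <- wilcoxon_compare(a + jitter, a)
  expect_equal(exact$p_value, 2 * 2^-30)

  withr::with_seed(9, {
    for (i in 1:20) {
      n <- sample(6:10, 1)
      x <- rnorm(n)
      y <- rnorm(n)
      # regenerate until rank ties are absent so the exact null applies
      while (anyDuplicated(abs(x - y)) || any(x == y)) {
        x <- rnorm(n)
        y <- rnorm(n)
      }
      got <- wilcoxon_compare(x, y)
      expect_equal(got$p_value, oracle_signed_rank_p(x, y))
    }
  })
})

test_that("run comparisons tier significance at 0.01 and 0.001", {
  base <- tidyr::expand_grid(iteration_id = 1:30,
                             level = c("slice", "patient"))
  a <- dplyr::mutate(base,
                     accuracy = 0.9 + iteration_id * 1e-4,
                     sensitivity = 0.8, specificity = 0.85, auroc = 0.95)
  b <- dplyr::mutate(a, accuracy = accuracy - 0.05)
  cmp <- compare_runs(a, b)
  acc <- cmp[cmp$metric == "accuracy", ]
  expect_true(all(acc$tier == "p<0.001"))
  expect_true(all(acc$stars == "***"))
  same <- cmp[cmp$metric == "sensitivity", ]
  expect_true(all(same$tier == "ns"))
  expect_equal(nrow(cmp), 8)  # 2 levels x 4 metrics
})

test_that("padded-vector baselines separate an easy cohort", {
  # positives: high plateau; negatives: low scores; varying lengths.  The
  # Youden threshold lands on the weakest training positive's score, so the
  # held-out positives are drawn at least as strong as the training ones
  # (and held-out negatives at least as weak) to keep the cohort separable
  # at that operating point.
  make_cohort <- function(ids, positive, seed, pos_range, neg_range) {
    withr::with_seed(seed, {
      purrr::map_dfr(seq_along(ids), function(i) {
        n <- sample(6:12, 1)
        rng <- if (positive[i]) pos_range else neg_range
        tibble::tibble(patient_id = ids[i], slice_index = seq_len(n) - 1L,
                       score = runif(n, rng[1], rng[2]))
      })
    })
  }
  train_pos <- c(rep(TRUE, 8), rep(FALSE, 8))
  train <- make_cohort(sprintf("TR%02d", 1:16), train_pos, 1,
                       pos_range = c(0.55, 0.95), neg_range = c(0.05, 0.45))
  test_pos <- c(rep(TRUE, 4), rep(FALSE, 4))
  test <- make_cohort(sprintf("TE%02d", 1:8), test_pos, 2,
                      pos_range = c(0.75, 0.95), neg_range = c(0.05, 0.25))
  tlabels <- tibble::tibble(patient_id = sprintf("TR%02d", 1:16),
                            patient_label = as.integer(train_pos))
  for (kind in c("random_forest", "svm")) {
    out <- baseline_patient_classifier(train, tlabels, test, kind = kind,
                                       seed = 4)
    expect_equal(out$patient_label, as.integer(test_pos))
    expect_equal(out$patient_id, sprintf("TE%02d", 1:8))
  }
})

test_that("zero padding appends only at the tail and checks lengths", {
  preds <- dplyr::bind_rows(
    tibble::tibble(patient_id = "A", slice_index = 0:3,
                   score = c(0.4, 0.3, 0.2, 0.1)),
    tibble::tibble(patient_id = "B", slice_index = 0:5, score = 1:6 / 10))
  x <- rpedetect:::pad_patient_vectors(preds, pad_length = 8)
  expect_equal(dim(x), c(2, 8))
  expect_equal(x["A", ], c(0.4, 0.3, 0.2, 0.1, 0, 0, 0, 0))
  expect_equal(x["B", ], c(1:6 / 10, 0, 0))
  # already at the padded length -> identity
  x6 <- rpedetect:::pad_patient_vectors(preds[preds$patient_id == "B", ],
                                        pad_length = 6)
  expect_equal(x6["B", ], 1:6 / 10)
  expect_error(rpedetect:::pad_patient_vectors(preds, pad_length = 5),
               "smaller than longest")
})
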