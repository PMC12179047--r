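# Shared fixtures and independent oracles, all built in code.

# brute-force oracle: maximum over all contiguous `w`-windows of the mean
oracle_window_max <- function(scores, w = 5L) {
  n <- length(scores)
  best <- -Inf
  for (i in seq_len(n - w + 1L)) {
    best <- max(best, mean(scores[i:(i + w - 1L)]))
  }
  best
}

# exhaustive Youden sweep over all candidate thresholds plus +/-Inf
# sentinels, rule "score >= t => positive", ties -> largest threshold
oracle_youden_threshold <- function(scores, labels) {
  cand <- c(-Inf, sort(unique(scores)), Inf)
  j <- vapply(cand, function(t) {
    pred <- as.integer(scores >= t)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, numeric(1))
  list(threshold = max(cand[j == max(j)]), j = max(j))
}

# pairwise Mann-Whitney AUROC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# exact two-sided signed-rank p-value by enumerating all sign assignments
# (tie- and zero-free differences only)
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# separable toy slices: flat noise (negative) vs bright horizontal band
# (positive), already standardized to [0, 1]
make_band_slices <- function(n, side = 128L, seed = 1L) {
  withr::with_seed(seed, {
    x <- array(0, c(side, side, n))
    labels <- rep_len(c(0L, 1L), n)
    rows <- as.integer(side * 0.4):as.integer(side * 0.5)
    for (k in seq_len(n)) {
      img <- matrix(runif(side * side, 0, 0.4), side, side)
      if (labels[k] == 1L) img[rows, ] <- img[rows, ] + 0.6
      x[, , k] <- standardize_slice(img, side)
    }
    list(x = x, labels = labels)
  })
}

# tiny phantom dataset for fast pipeline tests (desk-scale geometry)
tiny_dataset <- function(n_patients = 12L, seed = 7L, ...) {
  generate_dataset(phantom_config(
    n_patients = n_patients,
    slice_count_range = c(8L, 12L),
    matrix_size_choices = 64L,
    lesion_slab_length_range = c(2L, 5L),
    seed = seed, ...))
}

tiny_network <- function() network_config()

fast_training <- function(max_epochs = 3L, seed = 5L, ...) {
  training_config(max_epochs = max_epochs, seed = seed, ...)
}

# random prediction table for aggregation tests
random_predictions <- function(n_patients, min_slices = 5L, max_slices = 60L,
                               seed = 1L) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_patients), function(i) {
      n <- sample(min_slices:max_slices, 1)
      tibble::tibble(patient_id = sprintf("P%03d", i),
                     slice_index = seq_len(n) - 1L,
                     score = runif(n))
    })
  })
}
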