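#' Configuration of the U-Net-encoder slice classifier
#'
#' The classifier is the contracting path of a U-Net: `n_encoder_blocks`
#' repetitions of paired 3x3 same-padded convolutions (ReLU) followed by 2x2
#' max-pooling, then a flatten, the dense head, and a single sigmoid output
#' unit.  Filter counts are deliberately small so a full training run fits
#' on a laptop CPU; all widths are configurable.
#'
#' @param input_size side length of the (square) standardized input slice.
#' @param n_encoder_blocks number of conv-conv-pool blocks.
#' @param filters_per_block integer vector of channel counts, one per block.
#' @param dense_widths widths of the hidden dense layers after the flatten
#'   (the final 1-unit sigmoid layer is implicit).
#' @return An object of class `network_config`.
#' @export
network_config <- function(input_size = 128L,
                           n_encoder_blocks = 4L,
                           filters_per_block = c(2L, 4L, 8L, 16L),
                           dense_widths = 128L) {
  if (length(filters_per_block) != n_encoder_blocks) {
    abort("`filters_per_block` must have one entry per encoder block")
  }
  if (any(filters_per_block < 1L) || any(dense_widths < 1L)) {
    abort("layer widths must be positive")
  }
  structure(list(input_size = as.integer(input_size),
                 n_encoder_blocks = as.integer(n_encoder_blocks),
                 filters_per_block = as.integer(filters_per_block),
                 dense_widths = as.integer(dense_widths)),
            class = "network_config")
}

#' Training protocol configuration
#'
#' Binary cross-entropy loss with the Adam optimizer; training runs for at
#' most `max_epochs` epochs and halts early once the validation loss fails
#' to improve for `patience` consecutive epochs, restoring the weights with
#' the best validation loss seen.
#'
#' @param max_epochs maximum number of epochs (default 15).
#' @param patience early-stopping patience on validation loss (default 5).
#' @param batch_size minibatch size.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param seed integer governing weight initialization and data order.
#' @return An object of class `training_config`.
#' @export
training_config <- function(max_epochs = 15L, patience = 5L,
                            batch_size = 4L, learning_rate = 1e-3,
                            beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                            seed = 1L) {
  if (max_epochs < 1L) abort("`max_epochs` must be at least 1")
  if (patience < 1L) abort("`patience` must be at least 1")
  structure(list(loss = "binary_crossentropy", optimizer = "adam",
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "training_config")
}

cfg_to_cpp <- function(config) {
  list(input_size = config$input_size,
       filters = config$filters_per_block,
       dense = config$dense_widths)
}

#' Build an (untrained) slice classifier
#'
#' Allocates He-initialized weights for the encoder-classifier described by
#' `config`.  The same `seed` always yields bit-identical initial
#' parameters.
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `rpe_cnn`.
#' @export
build_model <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  down <- 2L^config$n_encoder_blocks
  if (config$input_size %% down != 0L || config$input_size < down) {
    abort(sprintf(
      "input size %d is not divisible by 2^%d; cannot pool %d times",
      config$input_size, config$n_encoder_blocks, config$n_encoder_blocks))
  }
  weights <- cpp_init_weights(cfg_to_cpp(config), as.integer(seed))
  structure(list(config = config, weights = weights,
                 init_seed = as.integer(seed), trained = FALSE,
                 history = NULL, best_epoch = NA_integer_,
                 epochs_run = 0L),
            class = "rpe_cnn")
}

#' @export
print.rpe_cnn <- function(x, ...) {
  cat(sprintf(
    "<rpe_cnn> %s U-Net-encoder classifier: input %d, blocks %s, dense %s\n",
    if (x$trained) "trained" else "untrained",
    x$config$input_size,
    paste(x$config$filters_per_block, collapse = "/"),
    paste(x$config$dense_widths, collapse = "/")))
  if (x$trained) {
    cat(sprintf("  %d epoch(s) run, best validation loss %.5f at epoch %d\n",
                x$epochs_run, min(x$history$val_loss), x$best_epoch))
  }
  invisible(x)
}

n_parameters <- function(model) {
  sum(vapply(model$weights, length, numeric(1)))
}

#' Epoch at which early stopping halts a validation-loss trace
#'
#' Replays the stopping rule on a prefix-complete loss trace: training halts
#' after the first epoch at which the validation loss has failed to improve
#' on the best value seen for `patience` consecutive epochs, and otherwise
#' runs all `max_epochs` epochs.  [train_model()] applies this exact rule.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience consecutive non-improving epochs tolerated.
#' @param max_epochs cap on the number of epochs.
#' @return The 1-based epoch index after which training stops.
#' @export
early_stopping_epoch <- function(val_losses, patience = 5L,
                                 max_epochs = length(val_losses)) {
  best <- Inf
  stalled <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
    }
    if (stalled >= patience) return(e)
    if (e >= max_epochs) return(e)
  }
  min(length(val_losses), max_epochs)
}

bce <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

as_slice_array <- function(x, input_size) {
  if (inherits(x, "volume_stack")) x <- preprocess_stack(x, input_size)
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L) abort("expected a 3-d slice array")
  if (dim(x)[1] != input_size || dim(x)[2] != input_size) {
    abort(sprintf("slice shape %d x %d does not match input size %d",
                  dim(x)[1], dim(x)[2], input_size))
  }
  x
}

#' Train the slice classifier
#'
#' Minibatch Adam on binary cross-entropy with per-epoch validation-loss
#' monitoring and early stopping (see [training_config()]).  The returned
#' model carries the parameter state with the best validation loss seen and
#' the full per-epoch loss history.  Training and validation sets must be
#' patient-disjoint; augmentation, if any, must have been applied to the
#' training slices only.
#'
#' @param model an untrained (or previously trained) [build_model()] object.
#' @param train_x 3-d array of standardized training slices.
#' @param train_y integer 0/1 slice labels for `train_x`.
#' @param val_x,val_y validation slices and labels.
#' @param config a [training_config()].
#' @return The trained `rpe_cnn` with `history`, `best_epoch`, `epochs_run`.
#' @export
train_model <- function(model, train_x, train_y, val_x, val_y,
                        config = training_config()) {
  stopifnot(inherits(model, "rpe_cnn"), inherits(config, "training_config"))
  train_x <- as_slice_array(train_x, model$config$input_size)
  val_x <- as_slice_array(val_x, model$config$input_size)
  if (dim(train_x)[3] == 0L) abort("empty training set")
  if (length(train_y) != dim(train_x)[3]) {
    abort("training labels do not match slice count")
  }
  if (length(unique(train_y)) < 2L) {
    warn("single-class training set; proceeding anyway")
  }
  cpp_cfg <- cfg_to_cpp(model$config)
  dtrain <- cpp_make_dataset(train_x)
  dval <- cpp_make_dataset(val_x)

  weights <- model$weights
  adam_m <- list()
  adam_v <- list()
  t_step <- 0L
  history <- tibble(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  best_weights <- weights
  best_epoch <- NA_integer_
  best_val <- Inf
  stalled <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    st <- cpp_train_epoch(weights, adam_m, adam_v, dtrain,
                          as.numeric(train_y), cpp_cfg,
                          config$learning_rate, config$beta1, config$beta2,
                          config$epsilon, config$batch_size,
                          derive_seed(config$seed, "shuffle", epoch), t_step)
    weights <- st$weights
    adam_m <- st$adam_m
    adam_v <- st$adam_v
    t_step <- st$t
    val_scores <- cpp_predict_scores(weights, dval, cpp_cfg, 4L)
    val_loss <- bce(val_scores, as.numeric(val_y))
    history <- dplyr::bind_rows(history, tibble(
      epoch = epoch, train_loss = st$train_loss, val_loss = val_loss))
    # the same rule early_stopping_epoch() replays on a full trace
    if (val_loss < best_val) {
      best_val <- val_loss
      best_weights <- weights
      best_epoch <- epoch
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
    }
    if (stalled >= config$patience) break
  }

  model$weights <- best_weights
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best_epoch
  model$epochs_run <- nrow(history)
  model$training_config <- config
  model
}

#' Score every slice of a stack
#'
#' Deterministic forward pass of the trained classifier; one probability per
#' slice, order preserved.
#'
#' @param model a trained [train_model()] object.
#' @param stack a [volume_stack()] (standardized on the fly) or a 3-d array
#'   of already standardized slices.
#' @param patient_id identifier attached to the output; defaults to the
#'   stack's own id when `stack` is a `volume_stack`.
#' @return Tibble `(patient_id, slice_index, score)` with `slice_index`
#'   0-based and `score` in `[0, 1]`.
#' @export
predict_slices <- function(model, stack, patient_id = NULL) {
  stopifnot(inherits(model, "rpe_cnn"))
  if (inherits(stack, "volume_stack") && is.null(patient_id)) {
    patient_id <- stack$patient_id
  }
  x <- as_slice_array(stack, model$config$input_size)
  scores <- cpp_predict_scores(model$weights, cpp_make_dataset(x),
                               cfg_to_cpp(model$config), 8L)
  tibble(patient_id = as.character(patient_id %||% "unknown"),
         slice_index = seq_len(dim(x)[3]) - 1L,
         score = scores)
}

#' @describeIn train_model per-epoch loss history as a tibble.
#' @param x an `rpe_cnn` model.
#' @param ... unused.
#' @export
tidy.rpe_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble(epoch = integer(), train_loss = numeric(),
                  val_loss = numeric()))
  }
  x$history
}

#' @describeIn train_model one-row model summary.
#' @export
glance.rpe_cnn <- function(x, ...) {
  tibble(trained = x$trained,
         n_parameters = n_parameters(x),
         epochs_run = x$epochs_run,
         best_epoch = x$best_epoch,
         best_val_loss = if (is.null(x$history)) NA_real_
                         else min(x$history$val_loss))
}

#' Save / load a trained model
#'
#' The parameter state is written as a JSON sidecar holding every weight
#' array at full precision together with the network and training
#' configuration and seeds, so a saved model is plain text and round-trips
#' exactly.
#'
#' @param model an `rpe_cnn`.
#' @param path output JSON path.
#' @return `path` invisibly for `save_model`; the restored `rpe_cnn` for
#'   `load_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rpe_cnn"))
  payload <- list(
    config = unclass(model$config),
    training_config = if (is.null(model$training_config)) NULL
                      else unclass(model$training_config),
    init_seed = model$init_seed,
    trained = model$trained,
    best_epoch = model$best_epoch,
    epochs_run = model$epochs_run,
    history = model$history,
    weights = lapply(model$weights, function(w) {
      list(dim = dim(w) %||% length(w), values = as.numeric(w))
    }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- network_config(p$config$input_size, p$config$n_encoder_blocks,
                        p$config$filters_per_block, p$config$dense_widths)
  weights <- lapply(p$weights, function(w) {
    if (length(w$dim) == 2L) matrix(w$values, w$dim[1], w$dim[2])
    else as.numeric(w$values)
  })
  model <- structure(
    list(config = cfg, weights = weights, init_seed = p$init_seed,
         trained = isTRUE(p$trained),
         history = if (is.null(p$history)) NULL else as_tibble(p$history),
         best_epoch = p$best_epoch %||% NA_integer_,
         epochs_run = p$epochs_run %||% 0L),
    class = "rpe_cnn")
  if (!is.null(p$training_config)) {
    model$training_config <- do.call(
      training_config,
      p$training_config[setdiff(names(p$training_config),
                                c("loss", "optimizer"))])
  }
  model
}
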