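#' Resize a square slice to the classifier input size
#'
#' Bilinear interpolation (via EBImage), with the output clamped to the
#' input's value range so interpolation cannot overshoot it.
#'
#' @param slice square numeric matrix.
#' @param target output side length in pixels (classifier default 128).
#' @return `target` x `target` numeric matrix.
#' @export
resize_slice <- function(slice, target = 128L) {
  if (!is.matrix(slice)) abort("`slice` must be a matrix")
  if (nrow(slice) != ncol(slice)) abort("non-square slice")
  if (nrow(slice) == target) return(slice)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(slice),
                                            w = target, h = target,
                                            filter = "bilinear"))
  dim(out) <- c(target, target)
  lo <- min(slice)
  hi <- max(slice)
  out[out < lo] <- lo
  out[out > hi] <- hi
  out
}

#' Min-max normalize a slice onto [0, 1]
#'
#' Applies `x -> (x - min x) / (max x - min x)` with the minimum and maximum
#' of the current slice (per-slice, not per-volume).  A constant slice maps
#' to all zeros.
#'
#' @param slice numeric matrix.
#' @return Matrix with values in `[0, 1]`; for a non-constant input the
#'   endpoints 0 and 1 are attained exactly.
#' @export
normalize_slice <- function(slice) {
  lo <- min(slice)
  hi <- max(slice)
  if (hi == lo) {
    return(matrix(0, nrow(slice), ncol(slice)))
  }
  (slice - lo) / (hi - lo)
}

#' Round values through IEEE single precision
#'
#' The pipeline stores standardized slices at float32 precision; this rounds
#' every value to its nearest single-precision representable (idempotent).
#'
#' @param x numeric vector, matrix or array.
#' @return Object of the same shape with float32-rounded values.
#' @export
to_single_precision <- function(x) {
  cpp_round_float32(as.numeric(x))
}

#' Standardize one slice for the classifier
#'
#' Resize to `target` x `target`, min-max normalize onto `[0, 1]`, then round
#' through single precision — in that order.
#'
#' @inheritParams resize_slice
#' @return Standardized `target` x `target` matrix.
#' @export
standardize_slice <- function(slice, target = 128L) {
  out <- to_single_precision(normalize_slice(resize_slice(slice, target)))
  matrix(out, target, target)
}

#' Standardize every slice of a volume stack
#'
#' @param volume a [volume_stack()].
#' @param target classifier input side length.
#' @return 3-d array `(target, target, n_slices)`, slice order preserved.
#' @export
preprocess_stack <- function(volume, target = 128L) {
  stopifnot(inherits(volume, "volume_stack"))
  out <- array(0, c(target, target, volume$n_slices))
  for (k in seq_len(volume$n_slices)) {
    out[, , k] <- standardize_slice(volume$slices[, , k], target)
  }
  out
}

#' The closed set of training-set augmentation kinds
#'
#' @return Character vector `c("none", "reflect_vertical", "rotate_90_cw",
#'   "blur_3x3")`.
#' @export
augmentation_kinds <- function() {
  c("none", "reflect_vertical", "rotate_90_cw", "blur_3x3")
}

#' Reflect a slice over the vertical axis
#'
#' Left-right mirror (anatomical midline flip); an involution.
#'
#' @param slice numeric matrix.
#' @return Mirrored matrix.
#' @export
reflect_vertical <- function(slice) {
  slice[, ncol(slice):1, drop = FALSE]
}

#' Rotate a square slice 90 degrees clockwise
#'
#' @param slice square numeric matrix.
#' @return Rotated matrix; applying it four times is the identity.
#' @export
rotate_90_cw <- function(slice) {
  if (nrow(slice) != ncol(slice)) abort("non-square slice")
  t(slice[nrow(slice):1, , drop = FALSE])
}

#' Blur a slice with a normalized 3x3 Gaussian kernel
#'
#' Separable `[1, 2, 1] %o% [1, 2, 1] / 16` kernel with replicated edges;
#' constant images are fixed points.
#'
#' @param slice numeric matrix.
#' @return Blurred matrix of the same size.
#' @export
blur_3x3 <- function(slice) {
  smooth_1d <- function(m) {
    n <- nrow(m)
    up <- m[c(1L, seq_len(n - 1L)), , drop = FALSE]
    down <- m[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
    (up + 2 * m + down) / 4
  }
  t(smooth_1d(t(smooth_1d(slice))))
}

apply_augmentation <- function(slice, kind) {
  switch(kind,
         none = slice,
         reflect_vertical = reflect_vertical(slice),
         rotate_90_cw = rotate_90_cw(slice),
         blur_3x3 = blur_3x3(slice),
         abort(sprintf("unknown augmentation kind '%s'", kind)))
}

#' Augment a training set of standardized slices
#'
#' For any kind other than `"none"`, the training set is doubled: every
#' original slice is kept and its augmented copy (carrying the same label)
#' is appended.  Augmentation is meant for the training partition only;
#' validation and test slices must never pass through this function.
#'
#' @param slices 3-d array `(h, w, n)` of standardized slices.
#' @param labels integer 0/1 vector of length `n`.
#' @param kind one of [augmentation_kinds()].
#' @return List with elements `slices` (array, `n` or `2n` slices) and
#'   `labels`.
#' @export
augment_training_set <- function(slices, labels,
                                 kind = c("reflect_vertical", "none",
                                          "rotate_90_cw", "blur_3x3")) {
  kind <- match.arg(kind)
  n <- if (length(dim(slices)) == 3L) dim(slices)[3] else 0L
  if (n != length(labels)) abort("slices and labels disagree in length")
  if (kind == "none" || n == 0L) {
    return(list(slices = slices, labels = as.integer(labels)))
  }
  out <- array(0, c(dim(slices)[1:2], 2L * n))
  out[, , seq_len(n)] <- slices
  for (k in seq_len(n)) {
    out[, , n + k] <- to_single_precision(
      apply_augmentation(slices[, , k], kind))
  }
  list(slices = out, labels = as.integer(c(labels, labels)))
}
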