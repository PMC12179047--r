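#' Construct a volume stack
#'
#' A volume stack holds one patient's ordered sequence of square axial
#' slices together with its acquisition geometry.  Slice order is fixed at
#' construction and preserved by every operation in the package; slice
#' indices are 0-based throughout.
#'
#' @param slices 3-d numeric array `(matrix_size, matrix_size, n_slices)`;
#'   the third axis is the acquisition (cranio-caudal) axis.
#' @param patient_id opaque patient identifier (scalar character).
#' @param pixel_pitch_mm in-plane pixel size in millimetres.
#' @param slice_spacing_mm distance between consecutive slices in millimetres.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(slices, patient_id,
                         pixel_pitch_mm = NA_real_,
                         slice_spacing_mm = NA_real_) {
  if (length(dim(slices)) == 2L) slices <- array(slices, c(dim(slices), 1L))
  if (length(dim(slices)) != 3L) abort("`slices` must be a 3-d array")
  if (dim(slices)[3] < 1L) abort("a volume stack needs at least one slice")
  if (dim(slices)[1] != dim(slices)[2]) {
    warn(sprintf("non-square in-plane dimensions (%d x %d); keeping as is",
                 dim(slices)[1], dim(slices)[2]))
  }
  structure(
    list(patient_id = as.character(patient_id),
         slices = slices,
         matrix_size = dim(slices)[1],
         n_slices = dim(slices)[3],
         pixel_pitch_mm = as.numeric(pixel_pitch_mm),
         slice_spacing_mm = as.numeric(slice_spacing_mm)),
    class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  cat(sprintf(
    "<volume_stack> patient %s: %d slices of %d x %d (pitch %.3f mm, spacing %.1f mm)\n",
    x$patient_id, x$n_slices, dim(x$slices)[1], dim(x$slices)[2],
    x$pixel_pitch_mm, x$slice_spacing_mm))
  invisible(x)
}

#' Read a 3-d MRI volume from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3-d scalar
#'   image.
#' @param patient_id identifier for the stack; defaults to the file name
#'   without extensions.
#' @return A [volume_stack()].
#' @export
read_volume <- function(path, patient_id = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    abort(sprintf("not a volume: %s has %d dimension(s), expected 3",
                  path, length(d)))
  }
  pd <- RNifti::pixdim(img)
  if (is.null(patient_id)) {
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  volume_stack(as.array(img), patient_id,
               pixel_pitch_mm = pd[1], slice_spacing_mm = pd[3])
}

#' Write a volume stack to a NIfTI file
#'
#' @param volume a [volume_stack()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_stack"))
  pd <- c(volume$pixel_pitch_mm, volume$pixel_pitch_mm, volume$slice_spacing_mm)
  pd[is.na(pd)] <- 1
  img <- RNifti::asNifti(volume$slices)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a weak-annotation table
#'
#' One row per patient with the patient-level RPE label and, for positive
#' patients, the uppermost and lowermost slice indices showing RPE.  Indices
#' are converted to the package's 0-based internal convention.
#'
#' @param path CSV file with columns `patient_id`, `patient_label`,
#'   `uppermost_idx`, `lowermost_idx` (index cells empty for negatives).
#' @param index_base base of the indices stored in the file (0 or 1).
#' @return A tibble with columns `patient_id` (character), `patient_label`
#'   (integer 0/1), `uppermost_idx`, `lowermost_idx` (integer, `NA` for
#'   negative patients), 0-based.
#' @export
read_annotations <- function(path, index_base = 0L) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "patient_label", "uppermost_idx", "lowermost_idx")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("annotation file lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  ann <- tibble(
    patient_id = as.character(raw$patient_id),
    patient_label = as.integer(raw$patient_label),
    uppermost_idx = suppressWarnings(as.integer(raw$uppermost_idx)) - index_base,
    lowermost_idx = suppressWarnings(as.integer(raw$lowermost_idx)) - index_base)
  validate_annotations(ann)
  ann
}

validate_annotations <- function(ann) {
  if (anyDuplicated(ann$patient_id)) {
    abort(sprintf("duplicate patient_id: %s",
                  paste(unique(ann$patient_id[duplicated(ann$patient_id)]),
                        collapse = ", ")))
  }
  if (!all(ann$patient_label %in% c(0L, 1L))) {
    abort("patient_label must be 0 or 1")
  }
  pos <- ann$patient_label == 1L
  if (any(pos & (is.na(ann$uppermost_idx) | is.na(ann$lowermost_idx)))) {
    abort("positive patient missing uppermost/lowermost slice indices")
  }
  if (any(!pos & (!is.na(ann$uppermost_idx) | !is.na(ann$lowermost_idx)))) {
    abort("negative patient carries slice indices")
  }
  bad <- pos & (ann$uppermost_idx > ann$lowermost_idx)
  if (any(bad)) {
    abort(sprintf("inverted index range for patient(s): %s",
                  paste(ann$patient_id[bad], collapse = ", ")))
  }
  if (any(pos & ann$uppermost_idx < 0L)) abort("negative slice index")
  invisible(ann)
}

#' Write a weak-annotation table
#'
#' @param annotations tibble as returned by [read_annotations()] (0-based).
#' @param path output CSV path.
#' @param index_base base to store indices in (0 or 1).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, index_base = 0L) {
  validate_annotations(annotations)
  out <- annotations
  out$uppermost_idx <- out$uppermost_idx + index_base
  out$lowermost_idx <- out$lowermost_idx + index_base
  write.csv(out[, c("patient_id", "patient_label",
                    "uppermost_idx", "lowermost_idx")],
            path, row.names = FALSE, na = "")
  invisible(path)
}

#' Expand one weak annotation into per-slice labels
#'
#' All slices between the uppermost and the lowermost annotated index
#' (inclusive at both ends) are labelled positive; every other slice, and
#' every slice of a negative patient, is labelled negative.
#'
#' @param patient_label 0/1 patient label.
#' @param uppermost_idx,lowermost_idx 0-based annotated range (ignored, and
#'   expected `NA`, for negative patients).
#' @param n_slices number of slices in the patient's stack.
#' @return Integer 0/1 vector of length `n_slices`.
#' @export
expand_annotation <- function(patient_label, uppermost_idx, lowermost_idx,
                              n_slices) {
  n_slices <- as.integer(n_slices)
  labels <- integer(n_slices)
  if (patient_label == 1L) {
    if (is.na(uppermost_idx) || is.na(lowermost_idx)) {
      abort("positive annotation without slice indices")
    }
    if (uppermost_idx > lowermost_idx) abort("inverted index range")
    if (uppermost_idx < 0L || lowermost_idx >= n_slices) {
      abort(sprintf("annotated range [%d, %d] out of range for %d slices",
                    uppermost_idx, lowermost_idx, n_slices))
    }
    labels[(uppermost_idx + 1L):(lowermost_idx + 1L)] <- 1L
  }
  labels
}

#' Expand a cohort's weak annotations into a slice-label table
#'
#' @param annotations annotation tibble (see [read_annotations()]).
#' @param slice_counts data frame with columns `patient_id` and `n_slices`.
#' @return Tibble with one row per slice: `patient_id`, `slice_index`
#'   (0-based), `label` (integer 0/1).
#' @export
expand_annotations <- function(annotations, slice_counts) {
  validate_annotations(annotations)
  ann <- dplyr::inner_join(annotations, slice_counts, by = "patient_id")
  if (nrow(ann) < nrow(annotations)) {
    abort("slice_counts missing for some annotated patients")
  }
  purrr::pmap_dfr(ann, function(patient_id, patient_label, uppermost_idx,
                                lowermost_idx, n_slices, ...) {
    tibble(patient_id = patient_id,
           slice_index = seq_len(n_slices) - 1L,
           label = expand_annotation(patient_label, uppermost_idx,
                                     lowermost_idx, n_slices))
  })
}

#' Write per-slice predictions to a TSV file
#'
#' Scores are serialized at full double precision (17 significant digits) so
#' that [read_predictions()] inverts the file bit-exactly.
#'
#' @param predictions tibble with columns `patient_id`, `slice_index`,
#'   `score` and optionally `final_label`.
#' @param path output TSV path.
#' @param labels optional tibble `(patient_id, slice_index, final_label)` to
#'   be joined onto `predictions`; its patients must match exactly.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, labels = NULL) {
  preds <- as_tibble(predictions)
  if (!is.null(labels)) {
    if (!setequal(unique(preds$patient_id), unique(labels$patient_id))) {
      abort("mismatched patients between predictions and labels")
    }
    preds <- dplyr::left_join(
      dplyr::select(preds, -dplyr::any_of("final_label")),
      labels, by = c("patient_id", "slice_index"))
  }
  if (!"final_label" %in% names(preds)) preds$final_label <- NA_integer_
  preds <- dplyr::arrange(preds, .data$patient_id, .data$slice_index)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("patient_id\tslice_index\tscore\tfinal_label", con)
  if (nrow(preds) > 0) {
    writeLines(sprintf("%s\t%d\t%.17g\t%s", preds$patient_id,
                       preds$slice_index, preds$score,
                       ifelse(is.na(preds$final_label), "NA",
                              as.character(preds$final_label))), con)
  }
  invisible(path)
}

#' Read a per-slice prediction table written by [write_predictions()]
#'
#' @param path TSV path.
#' @return Tibble with columns `patient_id`, `slice_index`, `score`,
#'   `final_label`.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  tibble(patient_id = as.character(raw$patient_id),
         slice_index = as.integer(raw$slice_index),
         score = as.numeric(raw$score),
         final_label = as.integer(raw$final_label))
}
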