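#' Configuration of the synthetic neck-phantom generator
#'
#' The generator emulates the geometry of axial T2-weighted water-only neck
#' stacks: 26-60 slices per patient, square matrices of 256-512 pixels with
#' in-plane pitches of 0.342-0.781 mm and 4-6 mm slice spacing, roughly half
#' of the patients positive.  A positive patient carries a thin hyperintense
#' crescent ("retropharyngeal" band) at a fixed fractional in-plane position
#' spanning a contiguous slab of slices; the slab's first and last slice
#' indices become the weak annotation.
#'
#' @param n_patients cohort size.
#' @param positive_fraction fraction of patients with the lesion (default
#'   0.5, the observed patient-level prevalence).
#' @param slice_count_range inclusive range of slices per stack.
#' @param matrix_size_choices square matrix sizes sampled per patient.
#' @param pixel_pitch_range_mm in-plane pixel pitch range (mm).
#' @param slice_spacing_range_mm slice spacing range (mm).
#' @param background_intensity air intensity outside the neck ellipse.
#' @param tissue_intensity soft-tissue intensity inside the ellipse.
#' @param lesion_intensity_ratio lesion / tissue intensity ratio (1.8 by
#'   default; 1 produces the null phantom with no signal).
#' @param lesion_slab_length_range inclusive range of consecutive lesion
#'   slices per positive patient (RPE may span only 2-3 slices).
#' @param lesion_thickness_px radial thickness of the crescent in pixels at
#'   a 256-pixel matrix; scaled proportionally for other matrix sizes.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed; the whole cohort is reproducible bit-exactly
#'   from `(config, seed)`.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_patients = 60L,
                           positive_fraction = 0.5,
                           slice_count_range = c(26L, 60L),
                           matrix_size_choices = c(256L, 384L, 512L),
                           pixel_pitch_range_mm = c(0.342, 0.781),
                           slice_spacing_range_mm = c(4, 6),
                           background_intensity = 0.05,
                           tissue_intensity = 0.5,
                           lesion_intensity_ratio = 1.8,
                           lesion_slab_length_range = c(2L, 10L),
                           lesion_thickness_px = 6L,
                           noise_sd = 0.04,
                           seed = 1L) {
  if (positive_fraction < 0 || positive_fraction > 1) {
    abort("`positive_fraction` must lie in [0, 1]")
  }
  if (slice_count_range[1] < 1L || diff(slice_count_range) < 0) {
    abort("invalid `slice_count_range`")
  }
  if (lesion_slab_length_range[1] < 1L) {
    abort("lesion slab length must be at least 1")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    positive_fraction = positive_fraction,
    slice_count_range = as.integer(slice_count_range),
    matrix_size_choices = as.integer(matrix_size_choices),
    pixel_pitch_range_mm = pixel_pitch_range_mm,
    slice_spacing_range_mm = slice_spacing_range_mm,
    background_intensity = background_intensity,
    tissue_intensity = tissue_intensity,
    lesion_intensity_ratio = lesion_intensity_ratio,
    lesion_slab_length_range = as.integer(lesion_slab_length_range),
    lesion_thickness_px = as.integer(lesion_thickness_px),
    noise_sd = noise_sd,
    seed = as.integer(seed)), class = "phantom_config")
}

# in-plane geometry of one patient's phantom, in fractional coordinates
draw_geometry <- function() {
  list(cx = 0.5 + runif(1, -0.03, 0.03),
       cy = 0.52 + runif(1, -0.03, 0.03),
       ax = 0.34 * (1 + runif(1, -0.08, 0.08)),
       ay = 0.40 * (1 + runif(1, -0.08, 0.08)),
       lesion_r = 0.17 * (1 + runif(1, -0.08, 0.08)),
       lesion_halfspan = (55 + runif(1, -8, 8)) * pi / 180)
}

lesion_mask <- function(matrix_size, geom, thickness_px) {
  s <- matrix_size
  t_frac <- thickness_px * (s / 256) / s
  xv <- (seq_len(s) - 0.5) / s
  yv <- (seq_len(s) - 0.5) / s
  x <- matrix(xv, s, s)                 # rows: left-right
  y <- matrix(yv, s, s, byrow = TRUE)   # cols: anterior (small y) - posterior
  dxm <- x - geom$cx
  dym <- y - geom$cy
  r <- sqrt(dxm^2 + dym^2)
  ang <- atan2(dxm, -dym)  # 0 points anterior
  in_annulus <- abs(r - geom$lesion_r) <= t_frac / 2
  in_span <- abs(ang) <= geom$lesion_halfspan
  in_annulus & in_span
}

#' Generate one phantom slice
#'
#' Background (air) outside an elliptical neck cross-section, soft tissue
#' inside, and — when `has_lesion` — a thin hyperintense crescent at the
#' canonical retropharyngeal position, plus additive Gaussian noise.  Draws
#' from R's RNG stream; identical RNG states yield identical slices.
#'
#' @param matrix_size square side length in pixels.
#' @param has_lesion paint the crescent band?
#' @param config a [phantom_config()] (intensity/noise parameters).
#' @param geom per-patient geometry as drawn internally; defaults to the
#'   canonical un-jittered geometry.
#' @return `matrix_size` x `matrix_size` numeric matrix.
#' @export
generate_slice <- function(matrix_size, has_lesion,
                           config = phantom_config(), geom = NULL) {
  geom <- geom %||% list(cx = 0.5, cy = 0.52, ax = 0.34, ay = 0.40,
                         lesion_r = 0.17, lesion_halfspan = 55 * pi / 180)
  s <- as.integer(matrix_size)
  xv <- (seq_len(s) - 0.5) / s
  yv <- (seq_len(s) - 0.5) / s
  x <- matrix(xv, s, s)
  y <- matrix(yv, s, s, byrow = TRUE)
  inside <- ((x - geom$cx) / geom$ax)^2 + ((y - geom$cy) / geom$ay)^2 <= 1
  img <- matrix(config$background_intensity, s, s)
  img[inside] <- config$tissue_intensity
  if (has_lesion) {
    mask <- lesion_mask(s, geom, config$lesion_thickness_px) & inside
    img[mask] <- config$tissue_intensity * config$lesion_intensity_ratio
  }
  if (config$noise_sd > 0) {
    img <- img + matrix(rnorm(s * s, sd = config$noise_sd), s, s)
  }
  img
}

#' Generate one phantom patient
#'
#' Draws slice count, matrix size, pitches and per-patient geometry, then
#' paints the lesion (if positive) on a contiguous slab of slices whose
#' length is drawn from `lesion_slab_length_range` (re-drawn if it exceeds
#' the slice count) and whose position is uniform along the stack.  The
#' annotation records the slab's first and last 0-based indices.
#'
#' @param config a [phantom_config()].
#' @param is_positive does this patient carry the lesion?
#' @param patient_id identifier for the generated stack.
#' @return List with elements `volume` ([volume_stack()]), `annotation`
#'   (one-row tibble) and `params` (drawn generation parameters).
#' @export
resample1 <- function(x) x[sample.int(length(x), 1L)]

generate_patient <- function(config, is_positive, patient_id) {
  n_slices <- resample1(config$slice_count_range[1]:config$slice_count_range[2])
  msize <- resample1(config$matrix_size_choices)
  pitch <- runif(1, config$pixel_pitch_range_mm[1],
                 config$pixel_pitch_range_mm[2])
  spacing <- runif(1, config$slice_spacing_range_mm[1],
                   config$slice_spacing_range_mm[2])
  geom <- draw_geometry()
  upper <- NA_integer_
  lower <- NA_integer_
  lesion <- rep(FALSE, n_slices)
  if (is_positive) {
    repeat {
      len <- resample1(config$lesion_slab_length_range[1]:
                         config$lesion_slab_length_range[2])
      if (len <= n_slices) break
    }
    upper <- resample1(0:(n_slices - len))
    lower <- upper + len - 1L
    lesion[(upper + 1L):(lower + 1L)] <- TRUE
  }
  # the noise draw is the only per-slice randomness, so build the two
  # deterministic base images once and add noise slice by slice (identical
  # draws to calling generate_slice per slice)
  noiseless <- config
  noiseless$noise_sd <- 0
  base_neg <- generate_slice(msize, FALSE, noiseless, geom)
  base_pos <- if (is_positive) generate_slice(msize, TRUE, noiseless, geom)
  slices <- array(0, c(msize, msize, n_slices))
  for (k in seq_len(n_slices)) {
    base <- if (lesion[k]) base_pos else base_neg
    if (config$noise_sd > 0) {
      base <- base + matrix(rnorm(msize * msize, sd = config$noise_sd),
                            msize, msize)
    }
    slices[, , k] <- base
  }
  list(volume = volume_stack(slices, patient_id, pitch, spacing),
       annotation = tibble(patient_id = as.character(patient_id),
                           patient_label = as.integer(is_positive),
                           uppermost_idx = as.integer(upper),
                           lowermost_idx = as.integer(lower),
                           n_slices = as.integer(n_slices)),
       params = list(matrix_size = msize, pixel_pitch_mm = pitch,
                     slice_spacing_mm = spacing, geometry = geom))
}

cohort_statuses <- function(config) {
  n_pos <- round(config$n_patients * config$positive_fraction)
  c(rep(TRUE, n_pos), rep(FALSE, config$n_patients - n_pos))
}

#' Generate a phantom cohort
#'
#' `round(n_patients * positive_fraction)` positive patients followed by the
#' negatives, generated under `set.seed(config$seed)` so the cohort is
#' reproducible bit-exactly from `(config, seed)`.  When `dir` is given the
#' volumes are written as NIfTI files, the annotations as
#' `annotations.csv` and the per-patient generation parameters as
#' `manifest.json`.
#'
#' @param config a [phantom_config()].
#' @param dir optional output directory.
#' @param keep_volumes keep the raw volumes in the returned tibble's
#'   `volume` list-column?  Set `FALSE` with `dir` to bound memory for large
#'   cohorts.
#' @return Tibble with one row per patient: the annotation columns,
#'   `n_slices`, `matrix_size`, `pixel_pitch_mm`, `slice_spacing_mm`,
#'   `volume` (list-column of [volume_stack()] or `NULL`) and `path` (when
#'   written); the generator config is attached as attribute `"config"`.
#' @export
generate_cohort <- function(config = phantom_config(), dir = NULL,
                            keep_volumes = TRUE) {
  if (!keep_volumes && is.null(dir)) {
    abort("`keep_volumes = FALSE` requires `dir` so the volumes survive")
  }
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  statuses <- cohort_statuses(config)
  ids <- sprintf("P%03d", seq_along(statuses))
  rows <- vector("list", length(ids))
  manifest <- vector("list", length(ids))
  with_seed(config$seed, {
    for (i in seq_along(ids)) {
      pat <- generate_patient(config, statuses[i], ids[i])
      row <- pat$annotation
      row$matrix_size <- pat$params$matrix_size
      row$pixel_pitch_mm <- pat$params$pixel_pitch_mm
      row$slice_spacing_mm <- pat$params$slice_spacing_mm
      row$path <- NA_character_
      if (!is.null(dir)) {
        row$path <- file.path(dir, paste0(ids[i], ".nii.gz"))
        write_volume(pat$volume, row$path)
      }
      row$volume <- if (keep_volumes) list(pat$volume) else list(NULL)
      rows[[i]] <- row
      manifest[[i]] <- c(list(patient_id = ids[i],
                              positive = statuses[i]), pat$params)
    }
  })
  cohort <- dplyr::bind_rows(rows)
  attr(cohort, "config") <- config
  if (!is.null(dir)) {
    write_annotations(cohort[, c("patient_id", "patient_label",
                                 "uppermost_idx", "lowermost_idx")],
                      file.path(dir, "annotations.csv"))
    jsonlite::write_json(list(config = unclass(config), patients = manifest),
                         file.path(dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  cohort
}

#' Generate a phantom cohort already standardized for the classifier
#'
#' Identical draws to [generate_cohort()] (same RNG stream), but each
#' patient's stack is standardized to the classifier input size as soon as
#' it is generated and the native-resolution volume is discarded, bounding
#' memory for large cohorts.
#'
#' @param config a [phantom_config()].
#' @param input_size classifier input side length.
#' @return An `rpe_dataset`: list with `x` (named list of standardized
#'   arrays), `annotations` (tibble incl. `n_slices`) and `slice_labels`
#'   (tibble from [expand_annotations()]).
#' @export
generate_dataset <- function(config = phantom_config(), input_size = 128L) {
  statuses <- cohort_statuses(config)
  ids <- sprintf("P%03d", seq_along(statuses))
  x <- vector("list", length(ids))
  names(x) <- ids
  rows <- vector("list", length(ids))
  with_seed(config$seed, {
    for (i in seq_along(ids)) {
      pat <- generate_patient(config, statuses[i], ids[i])
      x[[i]] <- preprocess_stack(pat$volume, input_size)
      rows[[i]] <- pat$annotation
    }
  })
  annotations <- dplyr::bind_rows(rows)
  new_rpe_dataset(x, annotations, config)
}

new_rpe_dataset <- function(x, annotations, config = NULL) {
  slice_labels <- expand_annotations(
    annotations[, c("patient_id", "patient_label", "uppermost_idx",
                    "lowermost_idx")],
    annotations[, c("patient_id", "n_slices")])
  structure(list(x = x, annotations = annotations,
                 slice_labels = slice_labels, config = config),
            class = "rpe_dataset")
}

#' Standardize a generated or loaded cohort for the classifier
#'
#' Accepts a cohort tibble from [generate_cohort()]; volumes are taken from
#' the `volume` list-column when present, otherwise read back from the
#' `path` column.
#'
#' @param cohort cohort tibble.
#' @param input_size classifier input side length.
#' @return An `rpe_dataset` (see [generate_dataset()]).
#' @export
preprocess_cohort <- function(cohort, input_size = 128L) {
  x <- vector("list", nrow(cohort))
  names(x) <- cohort$patient_id
  for (i in seq_len(nrow(cohort))) {
    vol <- cohort$volume[[i]]
    if (is.null(vol)) {
      if (is.na(cohort$path[i])) abort("cohort carries neither volumes nor paths")
      vol <- read_volume(cohort$path[i], cohort$patient_id[i])
    }
    x[[i]] <- preprocess_stack(vol, input_size)
  }
  ann <- cohort[, c("patient_id", "patient_label", "uppermost_idx",
                    "lowermost_idx", "n_slices")]
  new_rpe_dataset(x, ann, attr(cohort, "config"))
}

#' @export
print.rpe_dataset <- function(x, ...) {
  cat(sprintf(
    "<rpe_dataset> %d patients (%d positive), %d standardized slices (%.1f%% positive)\n",
    nrow(x$annotations), sum(x$annotations$patient_label),
    nrow(x$slice_labels), 100 * mean(x$slice_labels$label)))
  invisible(x)
}
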