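# Domain types and I/O shared by the whole pipeline.
#
# A "tomogram study" is one subject's stack of equal-sized 2D grayscale
# slices with layout metadata: each slice belongs to a condition (rest or
# stress) and an anatomical axis (short, horizontal_long, vertical_long) and
# carries a within-axis index. The clinically standard display format has
# 96 slices: 2 conditions x (24 short + 12 horizontal-long + 12 vertical-long).

CONDITIONS <- c("rest", "stress")
AXES <- c("short", "horizontal_long", "vertical_long")
PAPER_AXIS_COUNTS <- c(short = 24L, horizontal_long = 12L, vertical_long = 12L)

#' Canonical tomogram slice layouts
#'
#' Returns the slice layout table for a study profile, in canonical order
#' (rest before stress; axes ordered short, horizontal_long, vertical_long;
#' ascending within-axis index). The `paper_conformant_96` profile is the
#' standard clinical display: 96 slices, 48 per condition, split
#' 24/12/12 across the three axes. The `reduced` profile is a desk-scale
#' 8-slice layout (2 short + 1 + 1 per condition) used for fast tests.
#'
#' @param profile `"paper_conformant_96"` or `"reduced"`.
#' @return A tibble with columns `condition`, `axis`, `slice_index`.
#' @examples
#' nrow(tomogram_layout("paper_conformant_96"))  # 96
#' @export
tomogram_layout <- function(profile = c("paper_conformant_96", "reduced")) {
  profile <- match.arg(profile)
  counts <- switch(profile,
    paper_conformant_96 = PAPER_AXIS_COUNTS,
    reduced = c(short = 2L, horizontal_long = 1L, vertical_long = 1L)
  )
  purrr::map_dfr(CONDITIONS, function(cond) {
    purrr::map_dfr(AXES, function(ax) {
      tibble(condition = cond, axis = ax,
             slice_index = seq_len(counts[[ax]]))
    })
  }) |>
    canonical_layout_order()
}

canonical_layout_order <- function(layout) {
  layout |>
    dplyr::mutate(
      condition = factor(.data$condition, levels = CONDITIONS),
      axis = factor(.data$axis, levels = AXES)
    ) |>
    dplyr::arrange(.data$condition, .data$axis, .data$slice_index) |>
    dplyr::mutate(
      condition = as.character(.data$condition),
      axis = as.character(.data$axis)
    )
}

#' Construct a tomogram study object
#'
#' Bundles a slice stack with its layout metadata after validation. Slices
#' are reordered into canonical layout order, so any input permutation of
#' the same slices yields an identical study.
#'
#' @param subject_id Subject identifier.
#' @param slices 3D array, `height x width x n_slices`, grayscale intensities.
#' @param layout Tibble with `condition`, `axis`, `slice_index` rows aligned
#'   with the third dimension of `slices`.
#' @param normalize Rescale intensities to \[0, 1\] by per-study min-max. A
#'   constant-intensity study maps to all zeros with a warning.
#' @param strict Require the full 96-slice paper-conformant layout.
#' @return An object of class `tomogram_study`: a list with `subject_id`,
#'   `slices` (canonically ordered array) and `layout` (tibble).
#' @export
tomogram_study <- function(subject_id, slices, layout,
                           normalize = TRUE, strict = FALSE) {
  stopifnot(is.array(slices), length(dim(slices)) == 3)
  layout <- as_tibble(layout)
  assert_cols(layout, c("condition", "axis", "slice_index"), "layout")
  if (nrow(layout) != dim(slices)[3]) {
    abort("layout rows must match the number of slices")
  }
  if (anyNA(layout$condition) || anyNA(layout$axis) || anyNA(layout$slice_index)) {
    abort("missing layout entry")
  }
  if (!all(layout$condition %in% CONDITIONS) || !all(layout$axis %in% AXES)) {
    abort("layout condition/axis outside the recognized vocabulary")
  }
  key <- paste(layout$condition, layout$axis, layout$slice_index)
  if (anyDuplicated(key)) {
    abort("duplicate layout entry")
  }
  if (strict && !layout_is_conformant(layout)) {
    abort("non-conformant layout: strict mode requires the 96-slice profile")
  }
  ord <- order(
    match(layout$condition, CONDITIONS),
    match(layout$axis, AXES),
    layout$slice_index
  )
  layout <- layout[ord, , drop = FALSE]
  slices <- slices[, , ord, drop = FALSE]
  if (normalize) {
    rng <- range(slices)
    if (diff(rng) == 0) {
      warn("constant-intensity study: min-max normalization maps it to all zeros")
      slices[] <- 0
    } else {
      slices <- (slices - rng[1]) / diff(rng)
    }
  }
  structure(
    list(subject_id = as.character(subject_id), slices = slices,
         layout = layout),
    class = "tomogram_study"
  )
}

layout_is_conformant <- function(layout) {
  ref <- tomogram_layout("paper_conformant_96")
  if (nrow(layout) != nrow(ref)) return(FALSE)
  a <- canonical_layout_order(layout)
  all(a$condition == ref$condition) && all(a$axis == ref$axis) &&
    all(a$slice_index == ref$slice_index)
}

#' @export
print.tomogram_study <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf(
    "<tomogram_study> subject %s: %d slices of %dx%d px (%d rest, %d stress)\n",
    x$subject_id, d[3], d[1], d[2],
    sum(x$layout$condition == "rest"), sum(x$layout$condition == "stress")
  ))
  invisible(x)
}

#' Read a survival table
#'
#' Reads a CSV with columns `subject_id`, `time_days`, `event` into a
#' validated tibble: one row per subject, positive follow-up times, binary
#' event indicators, no duplicated ids.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `subject_id` (character), `time_days`
#'   (double) and `event` (integer 0/1).
#' @export
read_survival_table <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(data, c("subject_id", "time_days", "event"), "survival table")
  data <- dplyr::mutate(
    data,
    subject_id = as.character(.data$subject_id),
    time_days = as.double(.data$time_days),
    event = as.integer(.data$event)
  )
  if (anyDuplicated(data$subject_id)) {
    abort("duplicate subject id in survival table")
  }
  assert_outcomes(data, "survival table")
  data[c("subject_id", "time_days", "event")]
}

#' Write a survival table
#'
#' Inverse of [read_survival_table()]; the round trip is exact.
#'
#' @param data Tibble with `subject_id`, `time_days`, `event`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(data, path) {
  assert_cols(data, c("subject_id", "time_days", "event"))
  readr::write_csv(data[c("subject_id", "time_days", "event")], path)
  invisible(path)
}

CLINICAL_COLS <- c("age", "sex", "diabetes", "hypertension",
                   "hyperlipidemia", "smoking")

#' Read a clinical covariate table
#'
#' Reads `subject_id,age,sex,diabetes,hypertension,hyperlipidemia,smoking`.
#' Rows with any missing value are rejected (the model has no missing-data
#' handling); binary flags must be coded 0/1.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the subject id and the six covariates.
#' @export
read_clinical_table <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(data, c("subject_id", CLINICAL_COLS), "clinical table")
  data <- dplyr::mutate(data, subject_id = as.character(.data$subject_id))
  if (anyNA(data[c("subject_id", CLINICAL_COLS)])) {
    abort("clinical table contains missing values")
  }
  flags <- c("sex", "diabetes", "hypertension", "hyperlipidemia", "smoking")
  for (col in flags) {
    if (!all(data[[col]] %in% c(0, 1))) {
      abort(sprintf("clinical flag '%s' must be 0/1", col))
    }
  }
  if (anyDuplicated(data$subject_id)) {
    abort("duplicate subject id in clinical table")
  }
  data[c("subject_id", CLINICAL_COLS)]
}

#' Read a tomogram manifest
#'
#' The manifest CSV lists one slice image per row:
#' `subject_id,file,condition,axis,slice_index`.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble of manifest rows.
#' @export
read_manifest <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(data, c("subject_id", "file", "condition", "axis", "slice_index"),
              "manifest")
  dplyr::mutate(
    data,
    subject_id = as.character(.data$subject_id),
    slice_index = as.integer(.data$slice_index)
  )
}

read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Load a tomogram study from manifest rows
#'
#' Assembles one subject's slice stack from its manifest rows. Slice image
#' files (8- or 16-bit grayscale PNG) are read, ordered canonically and
#' min-max normalized per study. All slices must share dimensions.
#'
#' @param manifest Manifest rows for a single subject (see [read_manifest()]).
#' @param image_dir Directory against which `file` entries are resolved.
#' @param strict Require the 96-slice paper-conformant layout.
#' @param normalize Per-study min-max rescaling to \[0, 1\].
#' @return A [tomogram_study()] object.
#' @export
load_tomogram_study <- function(manifest, image_dir = ".",
                                strict = FALSE, normalize = TRUE) {
  manifest <- as_tibble(manifest)
  assert_cols(manifest, c("subject_id", "file", "condition", "axis",
                          "slice_index"), "manifest")
  sid <- unique(manifest$subject_id)
  if (length(sid) != 1) abort("manifest rows must belong to a single subject")
  imgs <- lapply(file.path(image_dir, manifest$file), read_gray_png)
  dims <- vapply(imgs, function(m) dim(m), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("mismatched slice dimensions")
  }
  slices <- array(unlist(imgs), dim = c(dims[1, 1], dims[2, 1], length(imgs)))
  tomogram_study(
    sid, slices,
    manifest[c("condition", "axis", "slice_index")],
    normalize = normalize, strict = strict
  )
}

#' Load every study referenced by a manifest
#'
#' @param manifest Full manifest tibble (possibly many subjects).
#' @inheritParams load_tomogram_study
#' @return A tibble with columns `subject_id` and `study` (list column of
#'   [tomogram_study()] objects).
#' @export
load_tomogram_studies <- function(manifest, image_dir = ".",
                                  strict = FALSE, normalize = TRUE) {
  manifest |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(function(rows, key) {
      tibble(
        subject_id = key$subject_id,
        study = list(load_tomogram_study(
          dplyr::mutate(rows, subject_id = key$subject_id),
          image_dir, strict = strict, normalize = normalize
        ))
      )
    }) |>
    dplyr::bind_rows()
}

#' Write a tomogram study to disk
#'
#' Two on-disk dialects are supported and load back to identical studies:
#' `"png"` writes one grayscale PNG per slice plus manifest rows; `"array"`
#' writes a single plain-text container (flattened slice values as CSV lines
#' with a JSON layout header).
#'
#' @param study A [tomogram_study()] object (or an un-normalized one).
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"array"`.
#' @return For `"png"`, the manifest rows as a tibble; for `"array"`, the
#'   container path.
#' @export
write_tomogram_study <- function(study, dir, format = c("png", "array")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "png") {
    files <- sprintf(
      "%s_%03d_%s_%s_%02d.png",
      study$subject_id, seq_len(nrow(study$layout)),
      substr(study$layout$condition, 1, 2),
      vapply(strsplit(study$layout$axis, "_"), function(p) {
        paste(substr(p, 1, 1), collapse = "")
      }, character(1)),
      study$layout$slice_index
    )
    for (k in seq_along(files)) {
      img <- pmin(pmax(study$slices[, , k], 0), 1)
      png::writePNG(img, file.path(dir, files[k]))
    }
    tibble(
      subject_id = study$subject_id,
      file = files,
      condition = study$layout$condition,
      axis = study$layout$axis,
      slice_index = study$layout$slice_index
    )
  } else {
    path <- file.path(dir, paste0(study$subject_id, ".tomo"))
    header <- jsonlite::toJSON(list(
      subject_id = study$subject_id,
      height = dim(study$slices)[1],
      width = dim(study$slices)[2],
      layout = study$layout
    ), auto_unbox = TRUE, digits = NA)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(header), con)
    for (k in seq_len(dim(study$slices)[3])) {
      writeLines(paste(
        format(as.vector(study$slices[, , k]), digits = 17, scientific = TRUE,
               trim = TRUE),
        collapse = ","
      ), con)
    }
    path
  }
}

#' Read a tomogram study from a plain-text array container
#'
#' @param path Path written by `write_tomogram_study(format = "array")`.
#' @inheritParams load_tomogram_study
#' @return A [tomogram_study()] object.
#' @export
read_tomogram_container <- function(path, strict = FALSE, normalize = TRUE) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  layout <- as_tibble(header$layout)
  vals <- lapply(lines[-1], function(l) as.double(strsplit(l, ",")[[1]]))
  slices <- array(
    unlist(vals),
    dim = c(header$height, header$width, length(vals))
  )
  tomogram_study(header$subject_id, slices, layout,
                 normalize = normalize, strict = strict)
}

#' Split a cohort into a test set and cross-validation folds
#'
#' Reserves `round(n * test_fraction)` subjects (half away from zero) as the
#' held-out test cohort and partitions the rest into `k_folds` folds whose
#' sizes differ by at most one. The assignment is deterministic given the
#' seed, and no subject appears in more than one role.
#'
#' @param data Tibble with a `subject_id` column (other columns are kept).
#' @param test_fraction Fraction held out for testing, in (0, 1).
#' @param k_folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed controlling the random assignment.
#' @return The input tibble with an added `role` column: `"test"` or
#'   `"fold<k>"`.
#' @export
split_cohort <- function(data, test_fraction = 0.2, k_folds = 5, seed = 1) {
  assert_cols(data, "subject_id")
  n <- nrow(data)
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be in (0, 1)")
  }
  if (k_folds < 2) abort("k_folds must be >= 2")
  if (n < k_folds + 1) abort("too few subjects to split")
  if (anyDuplicated(data$subject_id)) abort("duplicate subject id")
  n_test <- as.integer(round_half_up(n * test_fraction))
  n_test <- max(1L, min(n - k_folds, n_test))
  perm <- with_seed(derive_seed(seed, "split_cohort"), sample.int(n))
  role <- character(n)
  role[perm[seq_len(n_test)]] <- "test"
  train_idx <- perm[(n_test + 1):n]
  role[train_idx] <- paste0("fold", rep_len(seq_len(k_folds),
                                            length(train_idx)))
  dplyr::mutate(data, role = role)
}
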