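#' Read a single-cell table
#'
#' Reads a per-cell table (one row per segmented cell) from CSV or, when the
#' path ends in `.parquet` and the arrow package is available, Parquet.
#' Required columns are `cell_id`, `sample_id`, `x_um`, `y_um` and one raw
#' mean-fluorescence-intensity column per panel marker. A `batch_id` column
#' (the TMA / staining batch) is added with value `"batch1"` if absent.
#' Any extra columns are preserved untouched.
#'
#' @param path Path to a CSV or Parquet file.
#' @param panel Character vector of marker names expected as intensity
#'   columns.
#' @return A tibble of cells with the panel stored as an attribute.
#' @export
read_cell_table <- function(path, panel) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  cells <- if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("reading Parquet requires the arrow package")
    }
    as_tibble(arrow::read_parquet(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!"batch_id" %in% names(cells)) cells$batch_id <- "batch1"
  validate_cell_table(cells, panel)
  set_panel(cells, panel)
}

#' Write a single-cell table
#'
#' Inverse of [read_cell_table()]: CSV by default, Parquet for `.parquet`
#' paths when arrow is available. Round-trips field-for-field.
#'
#' @param cells A cell tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("writing Parquet requires the arrow package")
    }
    arrow::write_parquet(cells, path)
  } else {
    readr::write_csv(cells, path, progress = FALSE)
  }
  invisible(path)
}

#' Validate a single-cell table
#'
#' Checks the schema and the core invariants: `cell_id` unique within each
#' sample, finite coordinates, and non-negative marker intensities.
#'
#' @inheritParams write_cell_table
#' @param panel Character vector of marker names.
#' @return `cells`, invisibly, when valid; otherwise an error describing the
#'   first violated invariant (offending columns or row numbers are named).
#' @export
validate_cell_table <- function(cells, panel) {
  assert_columns(cells, c("cell_id", "sample_id", "x_um", "y_um", panel),
                 where = "cell table")
  if (anyDuplicated(cells[, c("sample_id", "cell_id")]) > 0) {
    abort("cell_id values are not unique within sample_id")
  }
  bad_xy <- which(!is.finite(cells$x_um) | !is.finite(cells$y_um))
  if (length(bad_xy) > 0) {
    abort(sprintf("non-finite coordinates in row(s): %s",
                  paste(head(bad_xy, 5), collapse = ", ")))
  }
  for (m in panel) {
    v <- cells[[m]]
    if (!is.numeric(v)) abort(sprintf("intensity column '%s' is not numeric", m))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0) {
      abort(sprintf(
        "negative or non-finite intensity for marker '%s' in row(s): %s",
        m, paste(head(bad, 5), collapse = ", ")),
        class = "follicular_validation_error")
    }
  }
  invisible(cells)
}

#' Validate cohort metadata
#'
#' The metadata table maps each sample to its group label (e.g. pwMS /
#' preMS / control), anatomical site and follicle class. `individual_id` is
#' optional and is used by [qc_filter_samples()] to keep one image per
#' individual.
#'
#' @param meta A data frame with at least `sample_id` and `group`.
#' @param cells Optional cell table; if given, every `sample_id` present in
#'   `cells` must appear exactly once in `meta`.
#' @return `meta` as a tibble, invisibly validated.
#' @export
validate_cohort_meta <- function(meta, cells = NULL) {
  assert_columns(meta, c("sample_id", "group"), where = "cohort metadata")
  if (anyDuplicated(meta$sample_id) > 0) {
    abort("sample_id values in metadata are not unique")
  }
  if (!is.null(cells)) {
    missing <- setdiff(unique(cells$sample_id), meta$sample_id)
    if (length(missing) > 0) {
      abort(sprintf("sample(s) missing from metadata: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
  }
  as_tibble(meta)
}
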