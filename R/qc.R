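#' Quality-control filter on phenotyped samples
#'
#' Applies the two image-level QC rules: samples whose Unknown fraction
#' (among non-Excluded cells) is strictly greater than `unknown_frac_max`
#' are dropped, and when several retained samples share an
#' `individual_id` in the metadata, only the one with the lowest Unknown
#' fraction is kept (ties broken by sample id for determinism). The filter
#' is idempotent.
#'
#' @param cells Phenotyped cell tibble.
#' @param unknown_frac_max Strict upper bound on the Unknown fraction
#'   (default 0.30: a sample at exactly 30 percent is retained).
#' @param meta Optional metadata with `individual_id`; enables the
#'   one-image-per-individual rule.
#' @param one_per_individual Apply the per-individual selection (default
#'   TRUE when `meta` has `individual_id`).
#' @return List with `cells` (retained rows) and `report`, one row per
#'   input sample: `n_cells`, `unknown_frac`, `kept` and `reason`.
#' @export
qc_filter_samples <- function(cells, unknown_frac_max = 0.30, meta = NULL,
                              one_per_individual = TRUE) {
  assert_columns(cells, c("sample_id", "phenotype"), "cells")
  stats_ <- cells %>%
    group_by(.data$sample_id) %>%
    summarise(
      n_cells = dplyr::n(),
      unknown_frac = mean(.data$phenotype[.data$phenotype != "Excluded"] ==
                            "Unknown"),
      .groups = "drop")
  stats_$kept <- stats_$unknown_frac <= unknown_frac_max
  stats_$reason <- ifelse(stats_$kept, "",
                          sprintf("unknown fraction %.3f > %.2f",
                                  stats_$unknown_frac, unknown_frac_max))
  if (one_per_individual && !is.null(meta) &&
      "individual_id" %in% names(meta)) {
    stats_ <- stats_ %>%
      left_join(meta[, c("sample_id", "individual_id")], by = "sample_id")
    chosen <- stats_ %>%
      filter(.data$kept) %>%
      arrange(.data$unknown_frac, .data$sample_id) %>%
      group_by(.data$individual_id) %>%
      dplyr::slice(1) %>%
      pull(.data$sample_id)
    dropped <- stats_$kept & !stats_$sample_id %in% chosen
    stats_$kept[dropped] <- FALSE
    stats_$reason[dropped] <- "another image of the same individual has a lower unknown fraction"
    stats_$individual_id <- NULL
  }
  keep_ids <- stats_$sample_id[stats_$kept]
  list(cells = cells[cells$sample_id %in% keep_ids, ], report = stats_)
}
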