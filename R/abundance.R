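#' Cell-type abundance per sample and scope
#'
#' Counts, densities (cells per mm^2 of the scope's tissue area) and
#' proportions for every phenotype, per sample, in the whole image and in
#' each annotated compartment. Unknown and Excluded cells never enter
#' numerators; under the default denominator the proportion is relative to
#' all phenotyped (non-Unknown, non-Excluded) cells in the scope, under
#' `denominator = "lineage"` relative to the cell's parent lineage.
#'
#' Tissue areas come from `areas` (e.g. [compartment_areas()] or
#' [synthetic_areas()]); without them the whole-image area falls back to
#' the convex hull of the sample's cells and compartment densities are NA.
#'
#' @param cells Phenotyped cell tibble (with `compartment` for
#'   compartment scopes).
#' @param areas Optional tibble `compartment` / `area_mm2` (one per
#'   sample, or with a `sample_id` column).
#' @param denominator `"phenotyped"` (default) or `"lineage"`.
#' @param lineages Phenotype-to-lineage map, as from [gating_lineages()].
#' @return Tibble: `sample_id`, `scope`, `cell_type`, `n`, `area_mm2`,
#'   `density_mm2`, `prop`.
#' @export
abundance <- function(cells, areas = NULL,
                      denominator = c("phenotyped", "lineage"),
                      lineages = gating_lineages()) {
  denominator <- match.arg(denominator)
  assert_columns(cells, c("sample_id", "phenotype"), "cells")
  ph <- cells[!cells$phenotype %in% c("Unknown", "Excluded"), ]
  if (!"compartment" %in% names(ph)) ph$compartment <- "unassigned"

  scoped <- bind_rows(
    ph %>% mutate(scope = "whole"),
    ph %>% filter(.data$compartment %in% compartment_levels()) %>%
      mutate(scope = .data$compartment))

  counts <- scoped %>%
    count(.data$sample_id, .data$scope, .data$phenotype, name = "n") %>%
    rename(cell_type = "phenotype") %>%
    tidyr::complete(.data$sample_id, .data$scope, .data$cell_type,
                    fill = list(n = 0L))

  # denominators
  if (denominator == "phenotyped") {
    den <- scoped %>% count(.data$sample_id, .data$scope, name = "n_den")
    counts <- counts %>% left_join(den, by = c("sample_id", "scope"))
  } else {
    den <- scoped %>%
      left_join(lineages, by = "phenotype") %>%
      count(.data$sample_id, .data$scope, .data$lineage, name = "n_den")
    counts <- counts %>%
      left_join(lineages, by = c(cell_type = "phenotype")) %>%
      left_join(den, by = c("sample_id", "scope", "lineage")) %>%
      select(-"lineage")
  }
  counts$n_den[is.na(counts$n_den)] <- 0L
  counts$prop <- ifelse(counts$n_den > 0, counts$n / counts$n_den, NA_real_)

  # areas
  if (!is.null(areas)) {
    areas <- as_tibble(areas)
    whole <- areas %>%
      group_by(across(any_of("sample_id"))) %>%
      summarise(area_mm2 = sum(.data$area_mm2), .groups = "drop") %>%
      mutate(scope = "whole")
    area_tbl <- bind_rows(areas %>% rename(scope = "compartment"), whole)
    by_ <- intersect(c("sample_id", "scope"), names(area_tbl))
    counts <- counts %>% left_join(area_tbl, by = by_)
  } else {
    hulls <- ph %>%
      group_by(.data$sample_id) %>%
      summarise(area_mm2 = hull_area_mm2(.data$x_um, .data$y_um),
                .groups = "drop") %>%
      mutate(scope = "whole")
    counts <- counts %>% left_join(hulls, by = c("sample_id", "scope"))
  }
  counts$density_mm2 <- ifelse(!is.na(counts$area_mm2) & counts$area_mm2 > 0,
                               counts$n / counts$area_mm2, NA_real_)
  counts %>%
    select("sample_id", "scope", "cell_type", "n", "area_mm2",
           "density_mm2", "prop") %>%
    arrange(.data$sample_id, .data$scope, .data$cell_type)
}

#' Tfh-to-Tfr ratio per compartment
#'
#' Ratio of Tfh cells to all FOXP3+ regulatory cells pooled within the
#' compartment (every Treg-lineage subset counts in the denominator). A
#' proxy for regulatory control over the follicular helper pool. Samples
#' with a zero denominator are returned with `ratio = NA` and a reason, so
#' they can be excluded from comparisons rather than imputed.
#'
#' @param cells Phenotyped cell tibble with `compartment`.
#' @param compartment Compartment to pool within (default `"mantle"`).
#' @param tfh_label Phenotype counted in the numerator.
#' @param treg_labels Treg-lineage phenotypes pooled in the denominator.
#' @return Tibble: `sample_id`, `compartment`, `n_tfh`, `n_treg`, `ratio`,
#'   `reason`.
#' @export
tfh_tfr_ratio <- function(cells, compartment = "mantle", tfh_label = "Tfh",
                          treg_labels = c("Tfr", "PD-1+ Treg", "PD-1- Tfr",
                                          "Treg")) {
  assert_columns(cells, c("sample_id", "phenotype", "compartment"), "cells")
  cells %>%
    filter(.data$compartment == !!compartment) %>%
    group_by(.data$sample_id) %>%
    summarise(n_tfh = sum(.data$phenotype == tfh_label),
              n_treg = sum(.data$phenotype %in% treg_labels),
              .groups = "drop") %>%
    tidyr::complete(sample_id = unique(cells$sample_id),
                    fill = list(n_tfh = 0L, n_treg = 0L)) %>%
    mutate(compartment = !!compartment,
           ratio = ifelse(.data$n_treg > 0, .data$n_tfh / .data$n_treg,
                          NA_real_),
           reason = ifelse(.data$n_treg > 0, "",
                           "no FOXP3+ Treg cells in compartment"))
}

#' Follicle-to-mantle ratio of a cell type
#'
#' Relative positioning of a cell type between the follicle and the mantle
#' zone: its abundance in the follicle divided by its abundance in the
#' mantle. The default basis is the proportion of phenotyped cells (robust
#' to area-estimation error but sensitive to the Unknown load of each
#' compartment); `basis = "density"` uses cells per mm^2 instead and is
#' invariant to adding Unknown cells.
#'
#' @param abund Output of [abundance()].
#' @param cell_type Cell type of interest (default `"Tfh"`).
#' @param basis `"proportion"` or `"density"`.
#' @return Tibble: `sample_id`, `cell_type`, `basis`, `follicle`,
#'   `mantle`, `ratio` (NA when the mantle value is zero or undefined).
#' @export
follicle_mantle_ratio <- function(abund, cell_type = "Tfh",
                                  basis = c("proportion", "density")) {
  basis <- match.arg(basis)
  col <- if (basis == "proportion") "prop" else "density_mm2"
  wide <- abund %>%
    filter(.data$cell_type == !!cell_type,
           .data$scope %in% c("follicle", "mantle")) %>%
    select("sample_id", "scope", value = all_of(col)) %>%
    tidyr::pivot_wider(names_from = "scope", values_from = "value")
  for (c_ in c("follicle", "mantle")) {
    if (!c_ %in% names(wide)) wide[[c_]] <- NA_real_
  }
  wide %>%
    mutate(cell_type = !!cell_type, basis = basis,
           ratio = ifelse(!is.na(.data$mantle) & .data$mantle > 0,
                          .data$follicle / .data$mantle, NA_real_)) %>%
    select("sample_id", "cell_type", "basis", "follicle", "mantle", "ratio")
}
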