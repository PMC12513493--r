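#' Run the full follicle analysis pipeline
#'
#' Chains the stages on a cohort of cell tables: marker calling, artifact
#' flagging, per-sample GMM binning of the configured markers, hierarchical
#' phenotyping, QC filtering, compartment assignment (manual/synthetic
#' polygons when given, otherwise the density surrogate per sample),
#' abundance and ratio tables, spatial distance and interaction statistics,
#' and (when `groups` is given) the two-group comparisons. Deterministic
#' given (config, seed): all stochastic stages draw child seeds from
#' `config$rng_seed`.
#'
#' @param cells Cell tibble for the cohort (validated against
#'   `config$panel`).
#' @param meta Cohort metadata (`sample_id`, `group`, optionally
#'   `individual_id`).
#' @param config A [pipeline_config()].
#' @param regions Optional: a single `region_set` shared by all samples
#'   (e.g. the synthetic geometry) or a named list per sample; if absent,
#'   [auto_annotate()] is run per sample.
#' @param areas Optional per-compartment areas (see [abundance()]);
#'   defaults to the regions' areas.
#' @param groups Optional two group labels to compare.
#' @param spatial Run the distance and interaction stages (default TRUE;
#'   abundance-only studies can turn them off).
#' @param compare_scopes Scopes used in the comparison stage (default
#'   whole image plus both follicular compartments).
#' @return Object of class `follicle_pipeline`: the phenotyped cells,
#'   per-stage result tables and a machine-readable run log (seed, config
#'   hash, per-stage cell counts in / out / excluded).
#' @export
run_pipeline <- function(cells, meta, config, regions = NULL, areas = NULL,
                         groups = NULL, spatial = TRUE,
                         compare_scopes = c("whole", "follicle", "mantle")) {
  if (is.null(cells) || nrow(cells) == 0) abort("no samples")
  validate_cell_table(cells, config$panel)
  meta <- validate_cohort_meta(meta, cells)
  cells <- set_panel(cells, config$panel)
  log_ <- list(seed = config$rng_seed, config_hash = rlang::hash(config),
               stages = list())
  note <- function(stage, n_in, n_out, n_excluded = n_in - n_out) {
    log_$stages[[stage]] <<- list(n_in = n_in, n_out = n_out,
                                  n_excluded = n_excluded)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            parent = e)
    })
  }
  n0 <- nrow(cells)

  cells <- run_stage("call_markers",
    call_markers(cells, config$thresholds, panel = config$panel,
                 gmm_markers = config$gmm_markers))
  cells <- run_stage("flag_artifacts",
    flag_artifacts(cells, quantile = config$artifact_quantile,
                   channel_frac = config$artifact_channel_frac,
                   panel = config$panel))
  for (m in config$gmm_markers) {
    cells <- run_stage(paste0("gmm_", m),
      add_gmm_calls(cells, marker = m, K = config$gmm_components,
                    seed = config$rng_seed,
                    min_cells = config$min_cells_gmm))
  }
  cells <- run_stage("assign_phenotypes", assign_phenotypes(cells))
  note("phenotype", n0, sum(cells$phenotype != "Excluded"),
       sum(cells$phenotype == "Excluded"))

  qc <- run_stage("qc_filter",
    qc_filter_samples(cells, unknown_frac_max = config$unknown_frac_max,
                      meta = meta))
  note("qc_filter", nrow(cells), nrow(qc$cells))
  cells <- qc$cells
  meta <- meta[meta$sample_id %in% unique(cells$sample_id), ]

  sample_ids <- unique(cells$sample_id)
  if (is.null(regions)) {
    regions <- lapply(split(cells, factor(cells$sample_id, levels = sample_ids)),
                      function(cs) run_stage("auto_annotate", auto_annotate(cs)))
  }
  if (inherits(regions, "region_set")) {
    cells <- run_stage("assign_compartments",
                       assign_compartments(cells, regions))
    areas <- areas %||% compartment_areas(regions)
  } else {
    cells <- run_stage("assign_compartments",
      bind_rows(lapply(sample_ids, function(sid) {
        assign_compartments(cells[cells$sample_id == sid, ], regions[[sid]])
      })))
    areas <- areas %||% bind_rows(lapply(sample_ids, function(sid) {
      mutate(compartment_areas(regions[[sid]]), sample_id = sid)
    }))
  }
  note("regions", nrow(cells),
       sum(cells$compartment != "unassigned"),
       sum(cells$compartment == "unassigned"))

  abund <- run_stage("abundance",
    abundance(cells, areas = areas,
              denominator = config$proportion_denominator))
  ratios <- run_stage("ratios", bind_rows(
    tfh_tfr_ratio(cells, "mantle"), tfh_tfr_ratio(cells, "follicle")))
  distances <- interactions <- NULL
  if (spatial) {
    distances <- run_stage("distances", avg_shortest_distance(cells))
    interactions <- run_stage("interactions",
      permutation_interaction_test(cells, k = config$k_neighbors,
                                   n_perm = config$n_permutations,
                                   seed = config$rng_seed))
  }
  comparisons <- NULL
  if (!is.null(groups)) {
    long <- bind_rows(
      abund %>% filter(.data$scope %in% compare_scopes) %>%
        select("sample_id", "scope", "cell_type", value = "density_mm2") %>%
        mutate(metric = "density"),
      abund %>% filter(.data$scope %in% compare_scopes) %>%
        select("sample_id", "scope", "cell_type", value = "prop") %>%
        mutate(metric = "proportion"),
      ratios %>%
        select("sample_id", scope = "compartment", value = "ratio") %>%
        mutate(metric = "tfh_tfr_ratio", cell_type = "Tfh/Treg"))
    comparisons <- run_stage("compare",
      compare_groups(long, meta = meta, groups = groups))
  }

  structure(list(cells = cells, meta = meta, regions = regions,
                 areas = areas, abundance = abund, ratios = ratios,
                 distances = distances, interactions = interactions,
                 comparisons = comparisons, qc_report = qc$report,
                 config = config, log = log_),
            class = "follicle_pipeline")
}

#' @export
print.follicle_pipeline <- function(x, ...) {
  cat("Follicle pipeline run\n")
  cat(sprintf("  samples: %d, cells retained: %d\n",
              length(unique(x$cells$sample_id)), nrow(x$cells)))
  cat(sprintf("  seed %d, config %s\n", x$log$seed, x$log$config_hash))
  for (s in names(x$log$stages)) {
    st <- x$log$stages[[s]]
    cat(sprintf("  %-12s in %6d out %6d excluded %5d\n",
                s, st$n_in, st$n_out, st$n_excluded))
  }
  invisible(x)
}

#' @export
glance.follicle_pipeline <- function(x, ...) {
  tibble(n_samples = length(unique(x$cells$sample_id)),
         n_cells = nrow(x$cells),
         frac_unknown = mean(x$cells$phenotype == "Unknown"),
         frac_excluded = mean(x$cells$phenotype == "Excluded"),
         seed = x$log$seed, config_hash = x$log$config_hash)
}

#' Write pipeline results to a directory
#'
#' Tidy CSV per result table plus a JSON run log, so a run is fully
#' inspectable outside R.
#'
#' @param result A `follicle_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cell_table(result$cells, file.path(dir, "cells_phenotyped.csv"))
  readr::write_csv(result$abundance, file.path(dir, "abundance.csv"))
  readr::write_csv(result$ratios, file.path(dir, "ratios.csv"))
  if (!is.null(result$distances)) {
    readr::write_csv(result$distances, file.path(dir, "distances.csv"))
    readr::write_csv(result$interactions, file.path(dir, "interactions.csv"))
  }
  if (!is.null(result$comparisons)) {
    readr::write_csv(result$comparisons, file.path(dir, "comparisons.csv"))
  }
  readr::write_csv(result$qc_report, file.path(dir, "qc_report.csv"))
  jsonlite::write_json(result$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
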