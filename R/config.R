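#' Pipeline configuration
#'
#' Bundles every tunable the pipeline uses so that a run is fully described
#' by (config, seed). Thresholds are per staining batch because positive
#' cut-offs are set per TMA; markers listed in `gmm_markers` are binned by a
#' per-sample Gaussian mixture instead of a fixed threshold.
#'
#' @param panel Ordered character vector of marker names.
#' @param thresholds Named list: `thresholds[[batch_id]][[marker]]` gives the
#'   positivity threshold (strict `>`) for each non-GMM marker.
#' @param gmm_markers Markers binned by the per-sample 5-component GMM
#'   (default `"BCL6"`).
#' @param k_neighbors Neighbourhood size for interaction scoring.
#' @param n_permutations Label permutations for the interaction null.
#' @param rng_seed Master seed; all stochastic stages derive deterministic
#'   child seeds per (stage, sample).
#' @param unknown_frac_max Samples with a strictly larger Unknown fraction
#'   are excluded by QC.
#' @param gmm_components Number of mixture components per GMM marker.
#' @param min_cells_gmm Minimum cells per sample for a GMM fit.
#' @param artifact_quantile,artifact_channel_frac Broadband-brightness
#'   artifact rule: flag cells above the sample's `artifact_quantile`
#'   intensity quantile in at least `artifact_channel_frac` of channels.
#' @param area_method How tissue area is obtained when computing densities
#'   without region polygons: `"hull"` (convex hull of cells) is the only
#'   fallback; with polygons their areas are used.
#' @param proportion_denominator `"phenotyped"` (all non-Unknown,
#'   non-Excluded cells in scope; default) or `"lineage"` (parent lineage).
#' @return A list with class `pipeline_config`.
#' @export
pipeline_config <- function(panel,
                            thresholds,
                            gmm_markers = "BCL6",
                            k_neighbors = 10,
                            n_permutations = 1000,
                            rng_seed = 1L,
                            unknown_frac_max = 0.30,
                            gmm_components = 5L,
                            min_cells_gmm = 50L,
                            artifact_quantile = 0.95,
                            artifact_channel_frac = 0.80,
                            area_method = c("hull", "region_polygons"),
                            proportion_denominator = c("phenotyped", "lineage")) {
  area_method <- match.arg(area_method)
  proportion_denominator <- match.arg(proportion_denominator)
  stopifnot(k_neighbors >= 1, n_permutations >= 1,
            unknown_frac_max > 0, unknown_frac_max < 1,
            gmm_components >= 2, min_cells_gmm >= 1)
  thresholded <- setdiff(panel, gmm_markers)
  for (b in names(thresholds)) {
    miss <- setdiff(thresholded, names(thresholds[[b]]))
    if (length(miss) > 0) {
      abort(sprintf("no threshold for batch '%s', marker(s): %s",
                    b, paste(miss, collapse = ", ")))
    }
  }
  structure(list(
    panel = panel, thresholds = thresholds, gmm_markers = gmm_markers,
    k_neighbors = as.integer(k_neighbors),
    n_permutations = as.integer(n_permutations),
    rng_seed = as.integer(rng_seed), unknown_frac_max = unknown_frac_max,
    gmm_components = as.integer(gmm_components),
    min_cells_gmm = as.integer(min_cells_gmm),
    artifact_quantile = artifact_quantile,
    artifact_channel_frac = artifact_channel_frac,
    area_method = area_method,
    proportion_denominator = proportion_denominator
  ), class = "pipeline_config")
}

#' Default pipeline configuration matched to the synthetic generator
#'
#' Thresholds sit at the midpoint (on the log scale) between the negative
#' and positive log-normal intensity components of [synthetic_config()], so
#' the default pipeline and generator form a self-consistent testbed.
#'
#' @param cfg A [synthetic_config()] (defaults to the default one).
#' @param batches Batch identifiers to register thresholds for.
#' @inheritParams pipeline_config
#' @return A `pipeline_config`.
#' @export
default_pipeline_config <- function(cfg = synthetic_config(),
                                    batches = "batch1", rng_seed = 1L, ...) {
  thr <- exp(cfg$log_mean_neg + cfg$marker_sep_sd * cfg$log_sd / 2)
  thresholded <- setdiff(cfg$panel, "BCL6")
  thresholds <- setNames(
    rep(list(setNames(rep(thr, length(thresholded)), thresholded)),
        length(batches)),
    batches)
  pipeline_config(panel = cfg$panel, thresholds = thresholds,
                  rng_seed = rng_seed, ...)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$thresholds <- lapply(raw$thresholds, function(b) unlist(b))
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$thresholds <- lapply(out$thresholds, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}
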