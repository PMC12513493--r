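#' Call thresholded markers
#'
#' Turns raw mean fluorescence intensities into boolean positivity calls
#' using per-batch manual thresholds: `call = intensity > threshold`
#' (strictly; a cell exactly at the threshold is negative). Alongside the
#' raw values a monotone 0-1 rescaling `x / (x + threshold)` is stored per
#' marker, anchoring the threshold at 0.5 so batches are comparable on a
#' common scale.
#'
#' @param cells Cell tibble with a `batch_id` column.
#' @param thresholds Named list `thresholds[[batch_id]][[marker]]`, as in
#'   [pipeline_config()].
#' @param panel Marker names; defaults to the table's panel attribute.
#' @param gmm_markers Markers to skip here (they are binned by
#'   [add_gmm_calls()] instead).
#' @return `cells` with `call_<marker>` (logical) and `scaled_<marker>`
#'   (numeric in (0, 1)) columns added.
#' @export
call_markers <- function(cells, thresholds, panel = NULL,
                         gmm_markers = "BCL6") {
  panel <- resolve_panel(cells, panel)
  if (!"batch_id" %in% names(cells)) cells$batch_id <- "batch1"
  markers <- setdiff(panel, gmm_markers)
  for (b in unique(cells$batch_id)) {
    thr_b <- thresholds[[b]]
    if (is.null(thr_b)) abort(sprintf("no thresholds for batch '%s'", b))
    miss <- setdiff(markers, names(thr_b))
    if (length(miss) > 0) {
      abort(sprintf("no threshold for batch '%s', marker(s): %s",
                    b, paste(miss, collapse = ", ")))
    }
  }
  thr_of <- function(b, m) vapply(b, function(bb) thresholds[[bb]][[m]],
                                  numeric(1), USE.NAMES = FALSE)
  for (m in markers) {
    thr <- thr_of(cells$batch_id, m)
    cells[[call_col(m)]] <- cells[[m]] > thr
    cells[[scaled_col(m)]] <- cells[[m]] / (cells[[m]] + thr)
  }
  cells
}

#' Flag broadband-bright artifact cells
#'
#' Erythrocyte-like autofluorescent debris is bright in every channel.
#' Cells whose intensity exceeds the sample's `quantile` quantile in at
#' least `channel_frac` of the panel markers are flagged; downstream
#' phenotyping labels them `"Excluded"` and the GMM binning ignores them.
#'
#' @param cells Cell tibble.
#' @param quantile Per-marker, per-sample intensity quantile (default 0.95).
#' @param channel_frac Minimum fraction of channels above that quantile
#'   (default 0.80).
#' @param panel Marker names; defaults to the table's panel attribute.
#' @return `cells` with a logical `artifact` column.
#' @export
flag_artifacts <- function(cells, quantile = 0.95, channel_frac = 0.80,
                           panel = NULL) {
  panel <- resolve_panel(cells, panel)
  art <- logical(nrow(cells))
  for (s in split(seq_len(nrow(cells)), cells$sample_id)) {
    above <- vapply(panel, function(m) {
      v <- cells[[m]][s]
      v > stats::quantile(v, probs = quantile, names = FALSE)
    }, logical(length(s)))
    if (is.null(dim(above))) above <- matrix(above, nrow = 1)
    art[s] <- rowMeans(above) >= channel_frac
  }
  cells$artifact <- art
  cells
}
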