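#' Per-sample Gaussian mixture binning of a marker
#'
#' Standardises a marker whose raw intensities are not comparable across
#' samples (staining efficiency, imaging conditions) by fitting a
#' K-component univariate Gaussian mixture to each sample's log-intensity
#' distribution and ranking the components by mean. With the default K = 5
#' the ordinal bins are labelled background, negative, low, medium, high;
#' cells in the "high" bin are considered positive.
#'
#' Intensities are log-transformed (zeros floored at the smallest positive
#' observed value), which makes bin assignments exactly invariant under
#' positive rescaling of the raw intensities. The EM fit (via mclust's
#' machinery, unequal variances) is run from multiple initialisations -
#' a quantile-anchored partition, a mass-guarded largest-gaps partition,
#' the SSE-optimal 1-D k-means partition (dynamic programming), and
#' `n_init` random k-means starts under the given seed - keeping the
#' highest-likelihood solution; single-start fits were observed to strand
#' rare components in local optima. Fitted components whose weight falls below
#' `collapse_weight` or whose means coincide within `collapse_tol` are
#' merged upward into their higher-mean neighbour, so every cell is always
#' binned and "high" is the top-mean surviving component.
#'
#' @param x Numeric vector of raw intensities for one sample (>= `min_cells`
#'   values, not all equal).
#' @param K Number of mixture components (default 5).
#' @param seed Seed for the k-means initialisations.
#' @param n_init Number of k-means starts.
#' @param min_cells Minimum number of cells required to fit.
#' @param collapse_weight,collapse_tol Component collapse rules.
#' @param marker,sample_id Labels carried into the result.
#' @return An object of class `gmm_binning`: fitted weights/means/sds (in
#'   rank order), per-cell `bin` (ordered factor) and logical `positive`
#'   (bin == "high"), plus fit metadata. `tidy()` gives one row per
#'   component; `glance()` one row per fit.
#' @export
fit_gmm_bins <- function(x, K = 5, seed = 1L, n_init = 10, min_cells = 50,
                         collapse_weight = 1e-3, collapse_tol = 1e-6,
                         marker = NA_character_, sample_id = NA_character_) {
  if (length(x) < min_cells) {
    abort(sprintf("fewer than %d cells (%d); sample below GMM floor",
                  min_cells, length(x)), class = "follicular_gmm_floor")
  }
  if (length(unique(x)) == 1) {
    abort("degenerate distribution: all intensities equal",
          class = "follicular_gmm_degenerate")
  }
  pos_min <- min(x[x > 0])
  lx <- log(pmax(x, pos_min))

  set.seed(seed)
  starts <- list()
  qs <- stats::quantile(lx, probs = seq(0.5 / K, 1 - 0.5 / K, length.out = K),
                        names = FALSE)
  starts[[1]] <- apply(abs(outer(lx, qs, "-")), 1, which.min)
  # largest-gaps start: cut the sorted values at the widest gaps that leave
  # a minimum mass on both sides (so stray tail points cannot form
  # singleton clusters); lands well-separated mixtures in the right basin
  n_x <- length(lx)
  min_seg <- max(10L, ceiling(0.002 * n_x))
  ord <- order(lx)
  gaps <- diff(lx[ord])
  cuts <- integer(0)
  for (g in order(gaps, decreasing = TRUE)) {
    if (length(cuts) == K - 1) break
    bounds <- sort(c(0L, cuts, n_x))
    if (min(abs(g - bounds)) >= min_seg) cuts <- c(cuts, g)
  }
  if (length(cuts) == K - 1) {
    gap_cl <- integer(n_x)
    gap_cl[ord] <- findInterval(seq_len(n_x), sort(cuts) + 1) + 1L
    starts[[length(starts) + 1]] <- gap_cl
  }
  # SSE-optimal 1-D k-means start (dynamic programming): deterministic and
  # reliably in the right basin for separated components
  xs <- lx[ord]
  if (n_x > 1000) {
    idx <- round(seq(1, n_x, length.out = 1000))
    seg <- ckmeans_dp_cpp(xs[idx], K)
    centers <- as.numeric(tapply(xs[idx], seg, mean))
    dp_cl <- apply(abs(outer(lx, centers, "-")), 1, which.min)
  } else {
    seg <- ckmeans_dp_cpp(xs, K)
    dp_cl <- integer(n_x)
    dp_cl[ord] <- seg
  }
  starts[[length(starts) + 1]] <- dp_cl
  for (i in seq_len(n_init)) {
    km <- tryCatch(suppressWarnings(kmeans(lx, centers = K, nstart = 1)),
                   error = function(e) NULL)
    if (!is.null(km)) starts[[length(starts) + 1]] <- km$cluster
  }
  # short-EM screening of every start, full EM only from the best one
  short_ctrl <- mclust::emControl(itmax = 15)
  best_short <- NULL
  for (cl in starts) {
    if (length(unique(cl)) < K) next
    z0 <- mclust::unmap(cl, groups = seq_len(K))
    fit <- tryCatch(mclust::meV(data = lx, z = z0, control = short_ctrl),
                    error = function(e) NULL)
    if (is.null(fit) || is.na(fit$loglik)) next
    if (is.null(best_short) || fit$loglik > best_short$loglik) best_short <- fit
  }
  if (is.null(best_short)) abort("GMM fit failed for all initialisations")
  best <- tryCatch(mclust::meV(data = lx, z = best_short$z),
                   error = function(e) NULL)
  if (is.null(best) || is.na(best$loglik)) best <- best_short

  w <- as.numeric(best$parameters$pro)
  mu <- as.numeric(best$parameters$mean)
  sd_ <- sqrt(as.numeric(best$parameters$variance$sigmasq))
  if (length(sd_) == 1) sd_ <- rep(sd_, K)
  comp <- apply(best$z, 1, which.max)

  # Collapse empty or duplicated components upward (into the nearest
  # higher-mean survivor) so the bin partition stays total.
  ord <- order(mu)
  keep <- rep(TRUE, K)
  for (r in seq_len(K - 1)) {
    i <- ord[r]
    if (w[i] < collapse_weight ||
        any(abs(mu[i] - mu[keep & seq_len(K) != i]) < collapse_tol)) {
      keep[i] <- FALSE
      target <- ord[which(ord == i) + 1]
      comp[comp == i] <- target
      w[target] <- w[target] + w[i]
    }
  }
  surv <- which(keep)
  surv <- surv[order(mu[surv])]
  m <- length(surv)
  lab_all <- c("background", "negative", "low", "medium", "high")
  labels <- if (m >= 5) lab_all[seq_len(m)] else c(head(lab_all, m - 1), "high")
  rank_of <- match(comp, surv)
  bins <- factor(labels[rank_of], levels = labels, ordered = TRUE)

  structure(list(
    marker = marker, sample_id = sample_id, K = as.integer(K),
    n = length(x), weights = w[surv], means = mu[surv], sds = sd_[surv],
    labels = labels, loglik = best$loglik, n_components = m,
    bin = bins, positive = bins == "high", seed = seed
  ), class = "gmm_binning")
}

#' @export
print.gmm_binning <- function(x, ...) {
  cat(sprintf("GMM binning of %s (sample %s): %d cells, %d component(s)\n",
              x$marker, x$sample_id, x$n, x$n_components))
  print(tibble(bin = x$labels, weight = round(x$weights, 4),
               log_mean = round(x$means, 3), log_sd = round(x$sds, 3)))
  invisible(x)
}

#' Add GMM-derived marker calls to a cell table
#'
#' Fits [fit_gmm_bins()] independently to every sample (on non-artifact
#' cells when an `artifact` column is present; artifacts are then binned by
#' the fitted model's boundaries) and adds `bin_<marker>` and
#' `call_<marker>` columns. Samples with fewer than `min_cells` cells are
#' not fitted: their bins and calls are set `NA`, which downstream gating
#' turns into `"Unknown"`, and the sample is listed in the
#' `attr(, "gmm_skipped")` attribute.
#'
#' @param cells Cell tibble.
#' @param marker Marker to bin (default `"BCL6"`).
#' @inheritParams fit_gmm_bins
#' @return `cells` with bin and call columns; fitted `gmm_binning` objects
#'   in `attr(, "gmm_fits")`.
#' @export
add_gmm_calls <- function(cells, marker = "BCL6", K = 5, seed = 1L,
                          n_init = 10, min_cells = 50) {
  n <- nrow(cells)
  bins <- rep(NA_character_, n)
  call <- rep(NA, n)
  fits <- list()
  skipped <- character(0)
  has_art <- "artifact" %in% names(cells)
  for (s in split(seq_len(n), cells$sample_id)) {
    sid <- cells$sample_id[s[1]]
    use <- if (has_art) s[!cells$artifact[s]] else s
    fit <- tryCatch(
      fit_gmm_bins(cells[[marker]][use], K = K,
                   seed = child_seed(seed, paste0("gmm_", marker), s[1]),
                   n_init = n_init, min_cells = min_cells,
                   marker = marker, sample_id = sid),
      follicular_gmm_floor = function(e) NULL)
    if (is.null(fit)) {
      skipped <- c(skipped, sid)
      next
    }
    bins[use] <- as.character(fit$bin)
    call[use] <- fit$positive
    if (has_art && length(s) > length(use)) {
      # bin artifact cells with the fitted boundaries (nearest mean in
      # posterior terms); they stay excluded from analysis regardless
      art <- setdiff(s, use)
      lx <- log(pmax(cells[[marker]][art], min(cells[[marker]][use][cells[[marker]][use] > 0])))
      post <- vapply(seq_along(fit$means), function(j) {
        log(fit$weights[j]) + dnorm(lx, fit$means[j], fit$sds[j], log = TRUE)
      }, numeric(length(art)))
      if (is.null(dim(post))) post <- matrix(post, nrow = 1)
      r <- apply(post, 1, which.max)
      bins[art] <- fit$labels[r]
      call[art] <- fit$labels[r] == "high"
    }
    fits[[sid]] <- fit
  }
  cells[[bin_col(marker)]] <- factor(bins,
    levels = c("background", "negative", "low", "medium", "high"),
    ordered = TRUE)
  cells[[call_col(marker)]] <- call
  attr(cells, "gmm_fits") <- fits
  attr(cells, "gmm_skipped") <- skipped
  cells
}

#' @export
tidy.gmm_binning <- function(x, ...) {
  tibble(marker = x$marker, sample_id = x$sample_id, bin = x$labels,
         weight = x$weights, log_mean = x$means, log_sd = x$sds)
}

#' @export
glance.gmm_binning <- function(x, ...) {
  tibble(marker = x$marker, sample_id = x$sample_id, n = x$n,
         n_components = x$n_components, loglik = x$loglik,
         frac_positive = mean(x$positive))
}
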