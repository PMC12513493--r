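#' k nearest neighbours of every point
#'
#' Exact Euclidean k-nearest-neighbour indices (self excluded), with
#' distance ties broken by lower index so results are deterministic.
#'
#' @param points Two-column matrix or data frame of coordinates (or a cell
#'   tibble with `x_um`/`y_um`).
#' @param k Number of neighbours; needs at least `k + 1` points.
#' @return Integer matrix, one row per point, columns ordered nearest
#'   first.
#' @export
knn_index <- function(points, k) {
  xy <- as_xy(points)
  if (nrow(xy) < k + 1) {
    abort(sprintf("need at least k + 1 = %d points, got %d", k + 1, nrow(xy)))
  }
  knn_brute_cpp(xy[, 1], xy[, 2], as.integer(k))
}

as_xy <- function(points) {
  if (is.data.frame(points) && all(c("x_um", "y_um") %in% names(points))) {
    cbind(points$x_um, points$y_um)
  } else {
    m <- as.matrix(points)
    stopifnot(ncol(m) == 2)
    m
  }
}

#' Average shortest distances between cell types
#'
#' For every ordered pair of phenotypes (A, B), the mean over A cells of
#' the Euclidean distance to the nearest B cell (nearest *other* cell for
#' A = B). The matrix is generally asymmetric. With `compartment` given,
#' only focal (A) cells in that compartment are averaged while candidate
#' neighbours may lie anywhere - neighbourhoods at compartment borders are
#' physically real. Pairs where either type is absent (or A has no cell in
#' the compartment) are flagged undefined.
#'
#' @param cells Phenotyped cell tibble (one or more samples).
#' @param types Phenotype universe (default: all observed except
#'   Excluded).
#' @param compartment Optional compartment filter for focal cells.
#' @return Tibble: `sample_id`, `type_a`, `type_b`, `mean_nn_um`, `n_a`,
#'   `n_b`, `defined`.
#' @export
avg_shortest_distance <- function(cells, types = NULL, compartment = NULL) {
  assert_columns(cells, c("sample_id", "x_um", "y_um", "phenotype"), "cells")
  types <- types %||% sort(setdiff(unique(cells$phenotype), "Excluded"))
  purrr::map(split(cells, cells$sample_id), function(cs) {
    idx_by_type <- lapply(types, function(tp) which(cs$phenotype == tp))
    names(idx_by_type) <- types
    focal_by_type <- idx_by_type
    if (!is.null(compartment)) {
      focal_by_type <- lapply(idx_by_type, function(i) {
        i[cs$compartment[i] %in% compartment]
      })
    }
    grid <- tidyr::expand_grid(type_a = types, type_b = types)
    grid$sample_id <- cs$sample_id[1]
    res <- purrr::pmap(grid[, c("type_a", "type_b")], function(type_a, type_b) {
      ia <- focal_by_type[[type_a]]
      ib <- idx_by_type[[type_b]]
      ok <- length(ia) > 0 && length(ib) > 0 &&
        !(type_a == type_b && length(ib) < 2)
      d <- if (ok) {
        mean(nn_min_dist_cpp(cs$x_um[ia], cs$y_um[ia],
                             cs$x_um[ib], cs$y_um[ib],
                             as.integer(ia), as.integer(ib)))
      } else NA_real_
      tibble(mean_nn_um = d, n_a = length(ia), n_b = length(ib), defined = ok)
    })
    bind_cols(grid, bind_rows(res))
  }) %>%
    bind_rows() %>%
    select("sample_id", "type_a", "type_b", "mean_nn_um", "n_a", "n_b",
           "defined")
}

#' Cohort-level average-distance matrix with clustering order
#'
#' Averages per-sample distance matrices over samples where the pair is
#' defined and orders the types by average-linkage hierarchical clustering
#' of the rows (the ordering used for distance heatmaps).
#'
#' @param asd Output of [avg_shortest_distance()].
#' @return Object of class `cohort_distance`: the matrix, the type order,
#'   and the `hclust` tree.
#' @export
cohort_distance_matrix <- function(asd) {
  agg <- asd %>%
    filter(.data$defined) %>%
    group_by(.data$type_a, .data$type_b) %>%
    summarise(mean_nn_um = mean(.data$mean_nn_um), .groups = "drop")
  types <- sort(unique(c(agg$type_a, agg$type_b)))
  m <- matrix(NA_real_, length(types), length(types),
              dimnames = list(types, types))
  m[cbind(agg$type_a, agg$type_b)] <- agg$mean_nn_um
  order_ <- seq_along(types)
  tree <- NULL
  if (length(types) > 2) {
    filled <- m
    filled[is.na(filled)] <- max(m, na.rm = TRUE)
    tree <- hclust(as.dist((filled + t(filled)) / 2), method = "average")
    order_ <- tree$order
  }
  structure(list(matrix = m, types = types[order_], hclust = tree),
            class = "cohort_distance")
}

#' Neighbourhood interaction test with a permutation null
#'
#' For each sample, each cell's neighbourhood is its `k` nearest cells; the
#' interaction score of an ordered pair (A, B) is the mean number of B
#' cells among the neighbours of A cells. The null distribution is
#' obtained by shuffling phenotype labels over cell positions within the
#' sample (`n_perm` times; positions, and compartments, stay put), giving
#' add-one empirical p-values for enrichment and depletion. The
#' `diff_score` column carries the legacy summary (observed minus permuted
#' mean, divided by `n_perm`); it is reported for comparability but is not
#' a probability - use `p_enrich` / `p_deplete` for inference.
#'
#' @param cells Phenotyped cell tibble; `"Excluded"` cells are dropped.
#' @param k Neighbourhood size (default 10).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Master seed; per-sample child seeds are derived.
#' @param compartment Optional: restrict focal (A) cells to this
#'   compartment; neighbours may be any cell.
#' @param types Label universe (default: all observed phenotypes except
#'   Excluded).
#' @param min_cells Pairs where either type has fewer cells than this are
#'   flagged `insufficient` (default 3).
#' @return Tibble per sample and ordered pair: `observed`, `perm_mean`,
#'   `perm_sd`, `p_enrich`, `p_deplete`, `diff_score`, `n_a`, `n_b`,
#'   `insufficient`.
#' @export
permutation_interaction_test <- function(cells, k = 10, n_perm = 1000,
                                         seed = 1L, compartment = NULL,
                                         types = NULL, min_cells = 3) {
  assert_columns(cells, c("sample_id", "x_um", "y_um", "phenotype"), "cells")
  cells <- cells[cells$phenotype != "Excluded", ]
  types <- types %||% sort(unique(cells$phenotype))
  samples <- unique(cells$sample_id)
  purrr::imap(split(cells, factor(cells$sample_id, levels = samples)),
              function(cs, sid) {
    cs <- cs[cs$phenotype %in% types, ]
    if (length(types) < 2) {
      abort(sprintf("sample %s: need at least 2 phenotypes in the universe",
                    sid))
    }
    if (nrow(cs) < k + 1) {
      abort(sprintf("sample %s: need at least k + 1 cells", sid))
    }
    nbr <- knn_index(cs, k)
    lab <- match(cs$phenotype, types) - 1L
    focal <- if (is.null(compartment)) rep(TRUE, nrow(cs)) else
      cs$compartment %in% compartment
    set.seed(child_seed(seed, "perm", match(sid, samples)))
    res <- perm_interaction_cpp(nbr, lab, focal, length(types),
                                as.integer(n_perm))
    counts <- tabulate(lab + 1L, nbins = length(types))
    grid <- tidyr::expand_grid(type_a = types, type_b = types)
    ia <- match(grid$type_a, types)
    ib <- match(grid$type_b, types)
    at <- cbind(ia, ib)
    tibble(
      sample_id = sid, type_a = grid$type_a, type_b = grid$type_b,
      observed = res$observed[at],
      perm_mean = res$perm_mean[at], perm_sd = res$perm_sd[at],
      p_enrich = (res$n_ge[at] + 1) / (res$n_valid[at] + 1),
      p_deplete = (res$n_le[at] + 1) / (res$n_valid[at] + 1),
      diff_score = (res$observed[at] - res$perm_mean[at]) / n_perm,
      n_a = res$n_focal[ia], n_b = counts[ib],
      k = k, n_perm = n_perm,
      insufficient = counts[ia] < min_cells | counts[ib] < min_cells)
  }) %>% bind_rows()
}

#' Compare interaction scores between two groups
#'
#' Per ordered pair, a two-sided unpaired Wilcoxon rank-sum test on the
#' per-sample observed scores between the two groups, Benjamini-Hochberg
#' adjusted across all tested pairs, with the direction (which group
#' scores higher) reported.
#'
#' @param scores Output of [permutation_interaction_test()] over a cohort.
#' @param meta Cohort metadata (`sample_id`, `group`).
#' @param groups Character vector of the two group labels to compare.
#' @return A `cohort_comparison` tibble: `type_a`, `type_b`, group sizes,
#'   `statistic`, `p`, `p_adj`, `direction`, `significant`.
#' @export
compare_interactions <- function(scores, meta, groups) {
  stopifnot(length(groups) == 2)
  df <- scores %>%
    filter(!.data$insufficient) %>%
    left_join(meta[, c("sample_id", "group")], by = "sample_id") %>%
    filter(.data$group %in% groups)
  long <- df %>%
    rename(metric = "type_a", cell_type = "type_b", value = "observed") %>%
    mutate(scope = "interaction",
           metric = paste(.data$metric, "->", .data$cell_type))
  out <- compare_groups(long[, c("sample_id", "metric", "scope",
                                 "cell_type", "value")],
                        meta = meta, groups = groups, family = "scope")
  out$pair <- out$metric
  out
}
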