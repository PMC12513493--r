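#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (`p_adj(i) = min over j >= i of
#' p(j) * n / j`, capped at 1), delegated to [stats::p.adjust()] after
#' input validation.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

wilcox_p <- function(x, y) {
  # exact when both groups are small and tie-free, otherwise normal
  # approximation with continuity and tie correction
  exact <- max(length(x), length(y)) <= 25 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  c(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Two-group comparison of per-sample metrics
#'
#' Unpaired two-sided Wilcoxon rank-sum tests of a per-sample metric table
#' between two groups, with Benjamini-Hochberg adjustment within families.
#' The default family is one `metric` x `scope` combination (one
#' figure-panel-like block of cell types); the family used is recorded in
#' the output so the adjustment universe is explicit.
#'
#' @param tbl Long tibble with columns `sample_id`, `metric`, `scope`,
#'   `cell_type` and `value`. `NA` values (e.g. undefined ratios) are
#'   dropped per row with the loss recorded in `n_excluded`.
#' @param meta Cohort metadata (`sample_id`, `group`).
#' @param groups The two group labels to compare; samples in other groups
#'   are ignored.
#' @param family Columns defining a BH family (default
#'   `c("metric", "scope")`).
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @return A `cohort_comparison` tibble: one row per (metric, scope,
#'   cell_type) with group sizes, Wilcoxon `statistic`, `p`, `p_adj`,
#'   `direction` (group with the higher median), `significant` and
#'   `family_id`.
#' @export
compare_groups <- function(tbl, meta, groups, family = c("metric", "scope"),
                           alpha = 0.05) {
  stopifnot(length(groups) == 2)
  assert_columns(tbl, c("sample_id", "metric", "scope", "cell_type", "value"),
                 "metric table")
  validate_cohort_meta(meta)
  df <- tbl %>%
    left_join(meta[, c("sample_id", "group")], by = "sample_id") %>%
    filter(.data$group %in% groups)
  sizes <- df %>% distinct(.data$sample_id, .data$group) %>%
    count(.data$group)
  if (nrow(sizes) < 2 || any(sizes$n < 2)) {
    abort("insufficient group size: need at least 2 samples per group")
  }
  out <- df %>%
    group_by(.data$metric, .data$scope, .data$cell_type) %>%
    summarise({
      ok <- !is.na(.data$value)
      x <- .data$value[ok & .data$group == groups[1]]
      y <- .data$value[ok & .data$group == groups[2]]
      if (length(x) >= 2 && length(y) >= 2) {
        wp <- wilcox_p(x, y)
        tibble(n_g1 = length(x), n_g2 = length(y),
               n_excluded = sum(!ok),
               statistic = wp[["statistic"]], p = wp[["p"]],
               direction = ifelse(median(x) >= median(y),
                                  groups[1], groups[2]))
      } else {
        tibble(n_g1 = length(x), n_g2 = length(y), n_excluded = sum(!ok),
               statistic = NA_real_, p = NA_real_,
               direction = NA_character_)
      }
    }, .groups = "drop")
  out$family_id <- do.call(paste, c(out[, family, drop = FALSE], sep = " | "))
  out <- out %>%
    group_by(.data$family_id) %>%
    mutate(p_adj = bh_adjust(.data$p)) %>%
    ungroup() %>%
    mutate(significant = !is.na(.data$p_adj) & .data$p_adj < alpha,
           group1 = groups[1], group2 = groups[2])
  class(out) <- c("cohort_comparison", class(out))
  out
}

#' @export
tidy.cohort_comparison <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.cohort_comparison <- function(x, ...) {
  tibble(n_tests = sum(!is.na(x$p)),
         n_significant = sum(x$significant, na.rm = TRUE),
         n_families = length(unique(x$family_id)),
         min_p_adj = suppressWarnings(min(x$p_adj, na.rm = TRUE)))
}
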