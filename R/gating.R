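#' Construct a gating tree
#'
#' A gating tree is an ordered table of boolean rules over marker calls.
#' Level 1 rules assign lineages; level 2 rules split a lineage into
#' subsets. Within a level, rules are evaluated top to bottom and the first
#' match wins, so rule order is part of the tree definition and is
#' serialised with results. Cells matching no rule are labelled
#' `"Unknown"`.
#'
#' @param rules A data frame with columns `level` (1 or 2), `parent`
#'   (lineage label for level-2 rules, `NA` for level 1), `label` (the
#'   phenotype assigned) and `rule` (an R expression over bare marker names,
#'   e.g. `"CD3 & CD4 & !CD8"`, evaluated against the boolean calls).
#' @return The rules as a tibble with class `gating_tree`.
#' @export
gating_tree <- function(rules) {
  rules <- as_tibble(rules)
  assert_columns(rules, c("level", "parent", "label", "rule"), "gating tree")
  if (any(!rules$level %in% c(1, 2))) abort("gating tree levels must be 1 or 2")
  bad <- rules$level == 2 & is.na(rules$parent)
  if (any(bad)) abort("level-2 gating rules must name a parent lineage")
  class(rules) <- c("gating_tree", class(rules))
  rules
}

#' Default follicular T/B cell gating tree
#'
#' Encodes the hierarchy used throughout the package. Lineages: Th
#' (CD3+CD4+CD8-FOXP3-), Treg (CD3+CD4+CD8-FOXP3+), Tc (CD3+CD8+CD4-),
#' B (CD20+CD3-); CD3+CD4+CD8+ double positives are excluded. Subsets:
#' Tfh (PD-1+ BCL6+, ICOS either), Tfh-like (PD-1+ BCL6-), ICOS+ Th
#' (ICOS+ PD-1-), triple-negative Th; Tfr (PD-1+ BCL6+), PD-1+ Treg,
#' PD-1- Tfr (BCL6+), Treg; Tfc (PD-1+ BCL6+), PD-1+ Tc, PD-1- Tc;
#' BCL6+ FoB, FoB (BCL6- CD21+), MB (CD27+), naive B (CD21- CD27-).
#'
#' ICOS is deliberately unconstrained for the Tfh and BCL6 for the ICOS+ Th
#' rule; because PD-1 rules are evaluated first the subsets stay disjoint.
#' Extra marker classes (stromal, endothelial, ...) can be supported by
#' appending rules rather than editing the defaults.
#'
#' @return A `gating_tree`.
#' @export
default_gating_tree <- function() {
  gating_tree(tibble(
    level = c(rep(1L, 5), rep(2L, 15)),
    parent = c(rep(NA_character_, 5),
               rep("Th", 4), rep("Treg", 4), rep("Tc", 3), rep("B", 4)),
    label = c("Excluded", "Th", "Treg", "Tc", "B",
              "Tfh", "Tfh-like", "ICOS+ Th", "Th",
              "Tfr", "PD-1+ Treg", "PD-1- Tfr", "Treg",
              "Tfc", "PD-1+ Tc", "PD-1- Tc",
              "BCL6+ FoB", "FoB", "MB", "Naive B"),
    rule = c(
      "CD3 & CD4 & CD8",
      "CD3 & CD4 & !CD8 & !FOXP3",
      "CD3 & CD4 & !CD8 & FOXP3",
      "CD3 & CD8 & !CD4",
      "CD20 & !CD3",
      # Th subsets
      "PD1 & BCL6",
      "PD1 & !BCL6",
      "ICOS & !PD1",
      "!PD1 & !BCL6 & !ICOS",
      # Treg subsets
      "PD1 & BCL6",
      "PD1 & !BCL6",
      "!PD1 & BCL6",
      "!PD1 & !BCL6",
      # Tc subsets
      "PD1 & BCL6",
      "PD1 & !BCL6",
      "!PD1",
      # B subsets
      "BCL6",
      "!BCL6 & CD21",
      "CD27",
      "!CD21 & !CD27"
    )
  ))
}

#' Lineage membership implied by a gating tree
#'
#' @param tree A `gating_tree`.
#' @return Tibble with `phenotype` and `lineage` (level-2 labels mapped to
#'   their parent; level-1 labels map to themselves).
#' @export
gating_lineages <- function(tree = default_gating_tree()) {
  lvl2 <- tree[tree$level == 2, c("label", "parent")]
  tibble(phenotype = c(lvl2$label, unique(tree$parent[!is.na(tree$parent)])),
         lineage = c(lvl2$parent, unique(tree$parent[!is.na(tree$parent)]))) %>%
    distinct(.data$phenotype, .keep_all = TRUE)
}

eval_rule <- function(rule, calls) {
  ok <- eval(parse(text = rule)[[1]], envir = calls, enclos = baseenv())
  ok & !is.na(ok)
}

#' Assign hierarchical phenotypes from marker calls
#'
#' Applies a gating tree to the boolean `call_*` columns produced by
#' [call_markers()] and [add_gmm_calls()]. Every cell receives exactly one
#' label: a subset phenotype, its lineage label when the lineage has no
#' subset rules,
#' `"Excluded"` (CD3+CD4+CD8+ triple positives or cells already flagged as
#' artifacts) or `"Unknown"`.
#'
#' @param cells Cell tibble with `call_<marker>` columns.
#' @param tree A [gating_tree()]; defaults to [default_gating_tree()].
#' @return `cells` with `phenotype` and `lineage` columns.
#' @export
assign_phenotypes <- function(cells, tree = default_gating_tree()) {
  markers <- unique(unlist(regmatches(tree$rule,
                                      gregexpr("[A-Za-z][A-Za-z0-9]*", tree$rule))))
  markers <- setdiff(markers, c("TRUE", "FALSE", "T", "F"))
  miss <- setdiff(call_col(markers), names(cells))
  if (length(miss) > 0) {
    abort(sprintf("missing marker call column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  calls <- as.list(cells[, call_col(markers)])
  names(calls) <- markers

  n <- nrow(cells)
  lineage <- rep(NA_character_, n)
  for (i in which(tree$level == 1)) {
    hit <- is.na(lineage) & eval_rule(tree$rule[i], calls)
    lineage[hit] <- tree$label[i]
  }
  phenotype <- rep(NA_character_, n)
  phenotype[is.na(lineage)] <- "Unknown"
  phenotype[!is.na(lineage) & lineage == "Excluded"] <- "Excluded"
  for (i in which(tree$level == 2)) {
    hit <- is.na(phenotype) & !is.na(lineage) & lineage == tree$parent[i] &
      eval_rule(tree$rule[i], calls)
    phenotype[hit] <- tree$label[i]
  }
  # Lineages with no subset rules keep their lineage label; cells of a
  # subdivided lineage that match no subset rule become Unknown.
  subdivided <- unique(tree$parent[tree$level == 2])
  open <- is.na(phenotype)
  phenotype[open & lineage %in% subdivided] <- "Unknown"
  phenotype[is.na(phenotype)] <- lineage[is.na(phenotype)]
  if ("artifact" %in% names(cells)) {
    phenotype[cells$artifact %in% TRUE] <- "Excluded"
  }
  cells$lineage <- dplyr::if_else(phenotype %in% c("Unknown", "Excluded"),
                                  phenotype, lineage)
  cells$phenotype <- phenotype
  cells
}
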