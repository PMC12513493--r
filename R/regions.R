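#' Density-based compartment annotation
#'
#' Reproducible surrogate for manual follicle/mantle/T-zone annotation from
#' CD21, CD20 and CD4 staining patterns. Three cell classes are formed from
#' the marker calls - follicular B (CD20+CD21+), mantle B (CD20+CD21-) and
#' T-zone (CD4+CD20-) - their densities are kernel-smoothed (Gaussian,
#' `bandwidth_um`) on a square grid (`grid_um` spacing), and each grid cell
#' takes the arg-max class. Cells are then labelled by the grid cell
#' containing them. Grid cells with negligible total density stay
#' unassigned. Manual polygons, when available, always take precedence over
#' this surrogate (pass them to [assign_compartments()] instead).
#'
#' @param cells Cell tibble for one sample with `call_CD20`, `call_CD21`
#'   and `call_CD4` columns.
#' @param bandwidth_um Gaussian kernel standard deviation (default 30).
#' @param grid_um Grid spacing (default 10).
#' @return A grid-based [region_set()] with provenance `"auto"`.
#' @export
auto_annotate <- function(cells, bandwidth_um = 30, grid_um = 10) {
  assert_columns(cells, c("x_um", "y_um", call_col(c("CD20", "CD21", "CD4"))),
                 "cells")
  if (length(unique(cells$sample_id %||% "s")) > 1) {
    abort("auto_annotate() works on one sample at a time")
  }
  cls <- with(cells, dplyr::case_when(
    call_CD20 & call_CD21 ~ "follicle",
    call_CD20 & !call_CD21 ~ "mantle",
    call_CD4 & !call_CD20 ~ "tzone",
    TRUE ~ NA_character_))

  pad <- 3 * bandwidth_um
  x_breaks <- seq(min(cells$x_um) - pad, max(cells$x_um) + pad, by = grid_um)
  y_breaks <- seq(min(cells$y_um) - pad, max(cells$y_um) + pad, by = grid_um)
  x_mid <- x_breaks[-length(x_breaks)] + grid_um / 2
  y_mid <- y_breaks[-length(y_breaks)] + grid_um / 2

  if (!any(cells$call_CD20)) {
    warn("no CD20+ cells: labelling the whole field tzone")
    lab <- matrix("tzone", length(x_mid), length(y_mid))
  } else {
    kx <- dnorm(outer(x_mid, cells$x_um, "-"), sd = bandwidth_um)
    ky <- dnorm(outer(y_mid, cells$y_um, "-"), sd = bandwidth_um)
    smooth_class <- function(class) {
      sel <- which(!is.na(cls) & cls == class)
      if (length(sel) == 0) {
        return(matrix(0, length(x_mid), length(y_mid)))
      }
      kx[, sel, drop = FALSE] %*% t(ky[, sel, drop = FALSE])
    }
    dens <- lapply(compartment_levels(), smooth_class)
    total <- Reduce(`+`, dens)
    m <- pmax(dens[[1]], dens[[2]], dens[[3]])
    # ties resolved in fixed order follicle > mantle > tzone
    which_max <- ifelse(dens[[1]] == m, 1L, ifelse(dens[[2]] == m, 2L, 3L))
    lab <- matrix(compartment_levels()[which_max],
                  length(x_mid), length(y_mid))
    floor_ <- 1e-6 * max(total)
    lab[total < floor_] <- NA_character_
  }

  structure(list(
    polygons = NULL, provenance = "auto",
    grid = list(x_breaks = x_breaks, y_breaks = y_breaks,
                x_mid = x_mid, y_mid = y_mid, label_matrix = lab,
                grid_um = grid_um, bandwidth_um = bandwidth_um)
  ), class = "region_set")
}

#' Classify a follicle as primary or secondary
#'
#' A follicle is called secondary (germinal-center containing) when both a
#' proliferation and a clustering signal are present among its B cells:
#' the Ki67+ fraction of follicle B cells is at least `ki67_frac_min`, and
#' at least `min_cluster_cells` BCL6+ B cells form one spatial cluster
#' under single-linkage at `linkage_um`. Otherwise it is primary. Both
#' thresholds are package defaults chosen for reproducibility, not
#' published cut-offs.
#'
#' @param cells One sample's cells with `phenotype`, `compartment`,
#'   `call_KI67` and `call_BCL6` columns.
#' @param ki67_frac_min Minimum Ki67+ fraction among follicle B cells.
#' @param min_cluster_cells Minimum BCL6+ B cells in one cluster.
#' @param linkage_um Single-linkage distance (micrometers).
#' @param b_labels Phenotype labels counted as B cells.
#' @return `"primary"`, `"secondary"`, or `"unknown"` (with a warning) when
#'   the follicle holds no B cells.
#' @export
classify_follicle <- function(cells, ki67_frac_min = 0.10,
                              min_cluster_cells = 20, linkage_um = 50,
                              b_labels = c("BCL6+ FoB", "FoB", "MB", "Naive B")) {
  assert_columns(cells, c("phenotype", "compartment",
                          call_col(c("KI67", "BCL6"))), "cells")
  fb <- cells[cells$compartment == "follicle" &
                cells$phenotype %in% b_labels, ]
  if (nrow(fb) == 0) {
    warn("no B cells in follicle: follicle class unknown")
    return("unknown")
  }
  ki67_ok <- mean(fb$call_KI67) >= ki67_frac_min
  bcl6_b <- fb[fb$call_BCL6 %in% TRUE, ]
  cluster_ok <- FALSE
  if (nrow(bcl6_b) >= min_cluster_cells) {
    hc <- hclust(stats::dist(bcl6_b[, c("x_um", "y_um")]), method = "single")
    sizes <- table(cutree(hc, h = linkage_um))
    cluster_ok <- any(sizes >= min_cluster_cells)
  }
  if (ki67_ok && cluster_ok) "secondary" else "primary"
}
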