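#' Construct a region set from labelled polygons
#'
#' A region set holds the compartment geometry of one field: labelled
#' polygons (follicle / mantle / tzone; outer ring plus optional holes) or,
#' for [auto_annotate()] output, a labelled grid. Polygon rings are
#' validated (at least 3 distinct vertices, closed - the closing vertex is
#' normalised away internally - and non-self-intersecting) and areas are
#' computed in mm^2 with holes subtracted.
#'
#' Nesting convention: when polygons overlap, a point belongs to the
#' smallest-area polygon containing it ("innermost wins"), which lets a
#' mantle ring be supplied either as an annulus with a hole or simply as a
#' larger disk drawn around the follicle.
#'
#' @param polygons Tibble with columns `polygon_id`, `compartment` and
#'   `rings` (list column; each element a list of 2-column matrices in
#'   micrometers, outer ring first).
#' @param provenance `"manual"`, `"auto"` or `"synthetic"`.
#' @return A list with class `region_set`.
#' @export
region_set <- function(polygons, provenance = "manual") {
  polygons <- as_tibble(polygons)
  assert_columns(polygons, c("polygon_id", "compartment", "rings"),
                 "region polygons")
  bad <- setdiff(unique(polygons$compartment), compartment_levels())
  if (length(bad) > 0) {
    abort(sprintf("unknown compartment label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  for (i in seq_len(nrow(polygons))) {
    polygons$rings[[i]] <- lapply(polygons$rings[[i]], clean_ring, i)
  }
  polygons$area_mm2 <- purrr::map_dbl(polygons$rings,
                                      ~um2_to_mm2(polygon_area_units(.x)))
  structure(list(polygons = polygons, provenance = provenance,
                 grid = NULL), class = "region_set")
}

# Validate one ring: drop the closing vertex, require >= 3 distinct
# vertices and no self-intersection (naive segment test).
clean_ring <- function(r, poly_index) {
  r <- as.matrix(r)
  if (nrow(r) >= 2 && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
  if (nrow(r) < 3 || abs(ring_area(r)) == 0) {
    abort(sprintf("invalid geometry in polygon %d: degenerate ring",
                  poly_index))
  }
  if (ring_self_intersects(r)) {
    abort(sprintf("invalid geometry in polygon %d: self-intersecting ring",
                  poly_index))
  }
  r
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

ring_self_intersects <- function(r) {
  n <- nrow(r)
  if (n <= 3) return(FALSE)
  nxt <- c(2:n, 1)
  for (i in seq_len(n - 2)) {
    js <- seq(i + 2, n)
    js <- js[!(i == 1 & js == n)]  # skip adjacent segments
    for (j in js) {
      if (segments_cross(r[i, ], r[nxt[i], ], r[j, ], r[nxt[j], ])) return(TRUE)
    }
  }
  FALSE
}

#' Read compartment polygons from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features, each with a
#' `compartment` property in follicle / mantle / tzone. Coordinates are in
#' micrometers. Additional rings of a Polygon are holes.
#'
#' @param path GeoJSON file path.
#' @return A [region_set()] with provenance `"manual"`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% abort("not a GeoJSON FeatureCollection")
  polys <- purrr::imap(feats, function(f, i) {
    comp <- f$properties$compartment
    if (is.null(comp)) abort(sprintf("polygon %d has no compartment label", i))
    if (!comp %in% compartment_levels()) {
      abort(sprintf("unknown compartment label '%s' in polygon %d", comp, i))
    }
    if (!identical(f$geometry$type, "Polygon")) {
      abort(sprintf("invalid geometry in polygon %d: expected Polygon, got %s",
                    i, f$geometry$type %||% "nothing"))
    }
    rings <- purrr::map(f$geometry$coordinates, function(ring) {
      do.call(rbind, purrr::map(ring, ~as.numeric(unlist(.x))))
    })
    tibble(polygon_id = f$properties$polygon_id %||% sprintf("%s_%d", comp, i),
           compartment = comp, rings = list(rings))
  })
  region_set(bind_rows(polys), provenance = "manual")
}

#' Write a polygon region set as GeoJSON
#'
#' @param regions A polygon-based `region_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  if (is.null(regions$polygons)) abort("grid-based region sets cannot be written as GeoJSON")
  feats <- purrr::pmap(regions$polygons[, c("polygon_id", "compartment", "rings")],
                       function(polygon_id, compartment, rings) {
    coords <- purrr::map(rings, function(r) {
      r <- rbind(r, r[1, ])  # close
      purrr::map(seq_len(nrow(r)), ~c(r[.x, 1], r[.x, 2]))
    })
    list(type = "Feature",
         properties = list(polygon_id = polygon_id, compartment = compartment),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Even-odd containment of points in one polygon (rings incl. holes),
# via mgcv's in.out on the NA-separated boundary.
points_in_polygon <- function(rings, x, y) {
  bnd <- do.call(rbind, purrr::map(rings, function(r) {
    rbind(r, r[1, ], c(NA, NA))
  }))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  mgcv::in.out(bnd, cbind(x, y))
}

# Is the filled interior of polygon `inner` contained in polygon `outer`?
# Tested on a deterministic grid of interior points of `inner`, so a hole in
# `outer` that already excludes `inner` (an annulus drawn around a disk)
# does not count as nesting.
poly_nested_in <- function(inner, outer, n_grid = 60, tol = 0.995) {
  v <- inner[[1]]
  gx <- seq(min(v[, 1]), max(v[, 1]), length.out = n_grid)
  gy <- seq(min(v[, 2]), max(v[, 2]), length.out = n_grid)
  pts <- cbind(rep(gx, times = n_grid), rep(gy, each = n_grid))
  keep <- points_in_polygon(inner, pts[, 1], pts[, 2])
  if (!any(keep)) return(FALSE)
  mean(points_in_polygon(outer, pts[keep, 1], pts[keep, 2])) >= tol
}

#' Compartment areas of a region set
#'
#' For polygon sets, the effective area of each polygon subtracts any
#' polygons nested inside it (consistent with innermost-wins assignment);
#' for auto-annotation grids, areas count labelled grid cells.
#'
#' @param regions A `region_set`.
#' @return Tibble with `compartment` and `area_mm2`.
#' @export
compartment_areas <- function(regions) {
  if (!is.null(regions$grid)) {
    g <- regions$grid
    tab <- table(factor(g$label_matrix, levels = compartment_levels()))
    return(tibble(compartment = names(tab),
                  area_mm2 = as.numeric(tab) * um2_to_mm2(g$grid_um^2)))
  }
  p <- regions$polygons
  eff <- p$area_mm2
  if (nrow(p) > 1) {
    for (i in seq_len(nrow(p))) {
      for (j in seq_len(nrow(p))) {
        if (i == j || p$area_mm2[j] >= p$area_mm2[i]) next
        if (poly_nested_in(p$rings[[j]], p$rings[[i]])) {
          eff[i] <- eff[i] - p$area_mm2[j]
        }
      }
    }
  }
  tibble(compartment = p$compartment, area_mm2 = pmax(eff, 0)) %>%
    group_by(.data$compartment) %>%
    summarise(area_mm2 = sum(.data$area_mm2), .groups = "drop")
}

#' Assign cells to compartments
#'
#' Labels every cell with the compartment containing it: by
#' innermost-containing-polygon for polygon region sets, or by grid lookup
#' for [auto_annotate()] output. Cells outside all regions are
#' `"unassigned"` (kept for whole-image statistics, excluded from
#' compartment statistics).
#'
#' @param cells Cell tibble.
#' @param regions A `region_set`.
#' @return `cells` with a `compartment` column.
#' @export
assign_compartments <- function(cells, regions) {
  n <- nrow(cells)
  if (!is.null(regions$grid)) {
    g <- regions$grid
    ix <- findInterval(cells$x_um, g$x_breaks, all.inside = TRUE)
    iy <- findInterval(cells$y_um, g$y_breaks, all.inside = TRUE)
    cells$compartment <- g$label_matrix[cbind(ix, iy)]
    cells$compartment[is.na(cells$compartment)] <- "unassigned"
    return(cells)
  }
  p <- regions$polygons
  comp <- rep("unassigned", n)
  best_area <- rep(Inf, n)
  for (i in seq_len(nrow(p))) {
    inside <- points_in_polygon(p$rings[[i]], cells$x_um, cells$y_um)
    take <- inside & p$area_mm2[i] < best_area
    comp[take] <- p$compartment[i]
    best_area[take] <- p$area_mm2[i]
  }
  cells$compartment <- comp
  cells
}
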