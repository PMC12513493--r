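#' Synthetic lymph-node follicle field configuration
#'
#' Describes the generative model for one tissue-microarray-core-sized
#' field (1.5 mm diameter by default): a central B-cell follicle disk, a
#' surrounding mantle annulus, the remaining T-cell zone, and optionally a
#' Ki67-rich germinal center (GC) disk inside the follicle. Cells of each
#' type are placed by a homogeneous Poisson process within their
#' compartment (complete spatial randomness, the null of the permutation
#' test), marker intensities are drawn from log-normal positive/negative
#' components, and BCL6 from a 5-component log-normal mixture. A
#' configurable fraction of broadband-bright artifact cells and of
#' marker-dim "Unknown" cells exercises the QC filters.
#'
#' Per-compartment, per-type densities are deliberately desk-scale
#' (a few thousand cells per field) and config-exposed; they are plausible
#' for follicular lymphoid tissue but are not measured values.
#'
#' @param field_radius_um Field (core) radius; default 750 (1.5 mm core).
#' @param follicle_radius_um Follicle disk radius; default 250.
#' @param mantle_width_um Mantle annulus width; default 60.
#' @param gc_present Whether a germinal center disk is present (secondary
#'   follicle); default TRUE.
#' @param gc_radius_um GC disk radius; default 120.
#' @param densities Tibble (`compartment`, `cell_type`, `per_mm2`) of
#'   expected cells per mm^2; defaults from [default_densities()].
#' @param gc_densities Tibble (`cell_type`, `per_mm2`) of extra density
#'   inside the GC disk (Ki67-high GC B cells and resident Tfh).
#' @param group_effects Nested list `group -> compartment -> cell_type ->
#'   multiplier` applied to densities; unlisted entries default to 1.
#' @param log_mean_neg,log_sd Log-normal negative component for thresholded
#'   markers; the positive component mean is `log_mean_neg +
#'   marker_sep_sd * log_sd`.
#' @param marker_sep_sd Separation between negative and positive
#'   log-intensity means, in units of `log_sd`; default 6 (see the methods
#'   vignette for why not 5).
#' @param bcl6_mixture List with `log_means`, `log_sds` (length 5, ranked
#'   background/negative/low/medium/high) for the BCL6 mixture; components
#'   are spaced 5 log-sd apart by default.
#' @param artifact_frac Expected fraction of broadband-bright artifacts
#'   (default 0.04, matching the artifact rate reported for this kind of
#'   data).
#' @param unknown_frac Expected fraction of lineage-marker-dim cells with
#'   no codable phenotype (default 0.05).
#' @param ki67_base_prob,gc_ki67_prob Ki67 positivity probability for
#'   ordinary cells and for GC B cells.
#' @param seed Default master seed for [simulate_cohort()].
#' @return A list with class `synthetic_config`.
#' @export
synthetic_config <- function(field_radius_um = 750,
                             follicle_radius_um = 250,
                             mantle_width_um = 60,
                             gc_present = TRUE,
                             gc_radius_um = 120,
                             densities = default_densities(),
                             gc_densities = default_gc_densities(),
                             group_effects = list(),
                             log_mean_neg = 1.5,
                             log_sd = 0.4,
                             marker_sep_sd = 6,
                             bcl6_mixture = default_bcl6_mixture(),
                             artifact_frac = 0.04,
                             unknown_frac = 0.05,
                             ki67_base_prob = 0.03,
                             gc_ki67_prob = 0.8,
                             seed = 1L) {
  mantle_outer <- follicle_radius_um + mantle_width_um
  if (!(gc_radius_um < follicle_radius_um &&
        mantle_outer < field_radius_um && follicle_radius_um > 0)) {
    abort("radii must be positive and nested: gc < follicle < follicle + mantle < field")
  }
  if (any(densities$per_mm2 < 0)) abort("densities must be non-negative")
  if (any(bcl6_mixture$log_sds <= 0) || log_sd <= 0) {
    abort("log-sds must be positive")
  }
  structure(list(
    field_radius_um = field_radius_um,
    follicle_radius_um = follicle_radius_um,
    mantle_width_um = mantle_width_um,
    gc_present = gc_present, gc_radius_um = gc_radius_um,
    densities = as_tibble(densities), gc_densities = as_tibble(gc_densities),
    group_effects = group_effects,
    log_mean_neg = log_mean_neg, log_sd = log_sd,
    marker_sep_sd = marker_sep_sd, bcl6_mixture = bcl6_mixture,
    artifact_frac = artifact_frac, unknown_frac = unknown_frac,
    ki67_base_prob = ki67_base_prob, gc_ki67_prob = gc_ki67_prob,
    panel = c("CD3", "CD4", "CD8", "FOXP3", "CD20", "CD21", "CD27",
              "PD1", "ICOS", "BCL6", "KI67"),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default per-compartment cell-type densities (cells per mm^2)
#'
#' B-cell-dominated follicle, naive/memory-B-dominated mantle, T-cell
#' dominated interfollicular zone, with follicular T subsets concentrated
#' in follicle and mantle.
#'
#' @return Tibble with columns `compartment`, `cell_type`, `per_mm2`.
#' @export
default_densities <- function() {
  d <- function(compartment, ...) {
    v <- c(...)
    tibble(compartment = compartment, cell_type = names(v), per_mm2 = unname(v))
  }
  bind_rows(
    d("follicle",
      "BCL6+ FoB" = 600, "FoB" = 900, "MB" = 150, "Naive B" = 150,
      "Tfh" = 250, "Tfh-like" = 150, "ICOS+ Th" = 80, "Th" = 150,
      "Tfr" = 60, "PD-1+ Treg" = 40, "PD-1- Tfr" = 30, "Treg" = 60,
      "Tfc" = 50, "PD-1+ Tc" = 60, "PD-1- Tc" = 80),
    d("mantle",
      "BCL6+ FoB" = 30, "FoB" = 150, "MB" = 600, "Naive B" = 1500,
      "Tfh" = 150, "Tfh-like" = 200, "ICOS+ Th" = 80, "Th" = 250,
      "Tfr" = 20, "PD-1+ Treg" = 40, "PD-1- Tfr" = 15, "Treg" = 150,
      "Tfc" = 30, "PD-1+ Tc" = 60, "PD-1- Tc" = 120),
    d("tzone",
      "BCL6+ FoB" = 5, "FoB" = 30, "MB" = 60, "Naive B" = 80,
      "Tfh" = 15, "Tfh-like" = 40, "ICOS+ Th" = 120, "Th" = 650,
      "Tfr" = 3, "PD-1- Tfr" = 3, "PD-1+ Treg" = 30, "Treg" = 120,
      "Tfc" = 5, "PD-1+ Tc" = 50, "PD-1- Tc" = 280,
      "DP T" = 5)
  )
}

#' @rdname default_densities
#' @export
default_gc_densities <- function() {
  tibble(cell_type = c("BCL6+ FoB", "Tfh"), per_mm2 = c(2000, 300))
}

#' Default 5-component BCL6 log-normal mixture
#'
#' Component log-means spaced 5 log-sd apart, ranked background, negative,
#' low, medium, high. Which component a cell draws from is set by its cell
#' type (BCL6+ types draw "high"); the per-sample pooled weights therefore
#' follow the field's composition, with background/negative dominating as
#' in tissue where most cells are BCL6-negative.
#'
#' @return List with `log_means`, `log_sds` and `labels`.
#' @export
default_bcl6_mixture <- function() {
  list(log_means = c(2, 4.5, 7, 9.5, 12), log_sds = rep(0.5, 5),
       labels = c("background", "negative", "low", "medium", "high"))
}

# Marker expression profile per cell type: which thresholded markers are
# positive (prob = 1), probabilistically positive (0 < p < 1), and which
# BCL6 component the type draws from ("high" for BCL6+ types; a categorical
# mix over the lower components otherwise).
type_profiles <- function() {
  prof <- function(pos = character(0), prob = numeric(0),
                   bcl6 = c(background = 1)) {
    list(pos = pos, prob = prob, bcl6 = bcl6)
  }
  th <- c("CD3", "CD4")
  list(
    "Th"        = prof(th),
    "ICOS+ Th"  = prof(c(th, "ICOS")),
    "Tfh"       = prof(c(th, "PD1"), prob = c(ICOS = 0.5), bcl6 = c(high = 1)),
    "Tfh-like"  = prof(c(th, "PD1"), prob = c(ICOS = 0.5),
                       bcl6 = c(negative = 1)),
    "Treg"      = prof(c(th, "FOXP3"), prob = c(ICOS = 0.3)),
    "PD-1+ Treg" = prof(c(th, "FOXP3", "PD1"), bcl6 = c(negative = 1)),
    "Tfr"       = prof(c(th, "FOXP3", "PD1"), prob = c(ICOS = 0.3),
                       bcl6 = c(high = 1)),
    "PD-1- Tfr" = prof(c(th, "FOXP3"), bcl6 = c(high = 1)),
    "PD-1- Tc"  = prof(c("CD3", "CD8")),
    "PD-1+ Tc"  = prof(c("CD3", "CD8", "PD1"), bcl6 = c(negative = 1)),
    "Tfc"       = prof(c("CD3", "CD8", "PD1"), bcl6 = c(high = 1)),
    "BCL6+ FoB" = prof(c("CD20", "CD21"), bcl6 = c(high = 1)),
    "FoB"       = prof(c("CD20", "CD21"),
                       bcl6 = c(negative = 0.5, low = 0.3, medium = 0.2)),
    "MB"        = prof(c("CD20", "CD27"), bcl6 = c(background = 0.6, low = 0.4)),
    "Naive B"   = prof("CD20"),
    "DP T"      = prof(c("CD3", "CD4", "CD8")),
    "Unknown"   = prof()
  )
}

sample_annulus <- function(n, r_in, r_out, centre) {
  r <- sqrt(runif(n, r_in^2, r_out^2))
  th <- runif(n, 0, 2 * pi)
  cbind(x = centre[1] + r * cos(th), y = centre[2] + r * sin(th))
}

compartment_radii <- function(cfg) {
  list(follicle = c(0, cfg$follicle_radius_um),
       mantle = c(cfg$follicle_radius_um,
                  cfg$follicle_radius_um + cfg$mantle_width_um),
       tzone = c(cfg$follicle_radius_um + cfg$mantle_width_um,
                 cfg$field_radius_um))
}

#' Analytic compartment of a point in the synthetic geometry
#'
#' @param x,y Coordinates in micrometers.
#' @param cfg A [synthetic_config()].
#' @return Character vector of compartments (`"unassigned"` outside the
#'   field).
#' @export
true_compartment_of <- function(x, y, cfg) {
  centre <- rep(cfg$field_radius_um, 2)
  r <- sqrt((x - centre[1])^2 + (y - centre[2])^2)
  rr <- compartment_radii(cfg)
  dplyr::case_when(
    r <= rr$follicle[2] ~ "follicle",
    r <= rr$mantle[2] ~ "mantle",
    r <= rr$tzone[2] ~ "tzone",
    TRUE ~ "unassigned")
}

#' Compartment areas of the synthetic geometry (mm^2)
#'
#' @inheritParams true_compartment_of
#' @return Tibble with `compartment` and `area_mm2`.
#' @export
synthetic_areas <- function(cfg) {
  rr <- compartment_radii(cfg)
  tibble(
    compartment = compartment_levels(),
    area_mm2 = um2_to_mm2(c(pi * rr$follicle[2]^2,
                            pi * (rr$mantle[2]^2 - rr$mantle[1]^2),
                            pi * (rr$tzone[2]^2 - rr$tzone[1]^2))))
}

effect_multiplier <- function(group_effects, group, compartment, cell_type) {
  g <- group_effects[[group]]
  if (is.null(g)) return(1)
  comp <- g[[compartment]]
  if (is.null(comp)) return(1)
  m <- comp[[cell_type]]
  if (is.null(m)) 1 else m
}

draw_marker_matrix <- function(n, types, cfg, seeded_ki67_prob) {
  panel <- cfg$panel
  profs <- type_profiles()
  mu_neg <- cfg$log_mean_neg
  mu_pos <- mu_neg + cfg$marker_sep_sd * cfg$log_sd
  out <- matrix(NA_real_, n, length(panel), dimnames = list(NULL, panel))
  bcl6_comp <- character(n)
  mix <- cfg$bcl6_mixture
  for (tp in unique(types)) {
    idx <- which(types == tp)
    p <- profs[[tp]]
    if (is.null(p)) abort(sprintf("no marker profile for cell type '%s'", tp))
    for (m in setdiff(panel, c("BCL6", "KI67"))) {
      state_pos <- if (m %in% p$pos) {
        rep(TRUE, length(idx))
      } else if (m %in% names(p$prob)) {
        runif(length(idx)) < p$prob[[m]]
      } else rep(FALSE, length(idx))
      out[idx, m] <- exp(rnorm(length(idx),
                               ifelse(state_pos, mu_pos, mu_neg), cfg$log_sd))
    }
    comp_lab <- sample(names(p$bcl6), length(idx), replace = TRUE,
                       prob = p$bcl6)
    ci <- match(comp_lab, mix$labels)
    out[idx, "BCL6"] <- exp(rnorm(length(idx), mix$log_means[ci],
                                  mix$log_sds[ci]))
    bcl6_comp[idx] <- comp_lab
  }
  ki_pos <- runif(n) < seeded_ki67_prob
  out[, "KI67"] <- exp(rnorm(n, ifelse(ki_pos, mu_pos, mu_neg), cfg$log_sd))
  list(intensity = out, bcl6_component = bcl6_comp, ki67_pos = ki_pos)
}

#' Simulate one follicle field
#'
#' Draws a labelled single-cell table for one field under the generative
#' model of [synthetic_config()], together with its ground truth (true
#' phenotype, compartment, BCL6 mixture component, artifact flag) aligned
#' row by row.
#'
#' @param cfg A [synthetic_config()].
#' @param group Group label used to look up `cfg$group_effects`.
#' @param sample_id Sample identifier.
#' @param seed Integer seed for this field.
#' @param batch_id Staining batch identifier.
#' @return List with `cells` (a validated cell tibble) and `truth`.
#' @export
simulate_sample <- function(cfg = synthetic_config(), group = "control",
                            sample_id = "S1", seed = 1L,
                            batch_id = "batch1") {
  set.seed(seed)
  centre <- rep(cfg$field_radius_um, 2)
  rr <- compartment_radii(cfg)
  areas <- synthetic_areas(cfg)

  lam <- cfg$densities %>%
    left_join(areas, by = "compartment") %>%
    mutate(mult = purrr::map2_dbl(.data$compartment, .data$cell_type,
             ~effect_multiplier(cfg$group_effects, group, .x, .y)),
           lambda = .data$per_mm2 * .data$area_mm2 * .data$mult)
  gc_area <- um2_to_mm2(pi * cfg$gc_radius_um^2)
  lam_gc <- if (cfg$gc_present) {
    cfg$gc_densities %>%
      mutate(mult = purrr::map_dbl(.data$cell_type,
               ~effect_multiplier(cfg$group_effects, group, "follicle", .x)),
             lambda = .data$per_mm2 * gc_area * .data$mult)
  } else NULL
  base_total <- sum(lam$lambda) + sum(lam_gc$lambda %||% 0)
  if (base_total < 10) abort("degenerate field: expected total cells < 10")

  pieces <- list()
  for (i in seq_len(nrow(lam))) {
    n_i <- rpois(1, lam$lambda[i])
    if (n_i == 0) next
    ring <- rr[[lam$compartment[i]]]
    xy <- sample_annulus(n_i, ring[1], ring[2], centre)
    pieces[[length(pieces) + 1]] <- tibble(
      x_um = xy[, 1], y_um = xy[, 2], cell_type = lam$cell_type[i],
      compartment = lam$compartment[i], in_gc = FALSE)
  }
  if (!is.null(lam_gc)) {
    for (i in seq_len(nrow(lam_gc))) {
      n_i <- rpois(1, lam_gc$lambda[i])
      if (n_i == 0) next
      xy <- sample_annulus(n_i, 0, cfg$gc_radius_um, centre)
      pieces[[length(pieces) + 1]] <- tibble(
        x_um = xy[, 1], y_um = xy[, 2], cell_type = lam_gc$cell_type[i],
        compartment = "follicle", in_gc = TRUE)
    }
  }
  # marker-dim Unknown cells, split over compartments by their base load
  other_frac <- 1 - cfg$unknown_frac - cfg$artifact_frac
  n_unknown <- rpois(1, base_total * cfg$unknown_frac / other_frac)
  if (n_unknown > 0) {
    comp_tot <- tapply(lam$lambda, lam$compartment, sum)
    comp_u <- sample(names(comp_tot), n_unknown, replace = TRUE,
                     prob = comp_tot)
    for (cp in unique(comp_u)) {
      idx <- comp_u == cp
      xy <- sample_annulus(sum(idx), rr[[cp]][1], rr[[cp]][2], centre)
      pieces[[length(pieces) + 1]] <- tibble(
        x_um = xy[, 1], y_um = xy[, 2], cell_type = "Unknown",
        compartment = cp, in_gc = FALSE)
    }
  }
  cells <- bind_rows(pieces)

  # broadband-bright artifacts, uniform over the whole field
  n_art <- rpois(1, base_total * cfg$artifact_frac / other_frac)
  if (n_art > 0) {
    xy <- sample_annulus(n_art, 0, cfg$field_radius_um, centre)
    cells <- bind_rows(cells, tibble(
      x_um = xy[, 1], y_um = xy[, 2], cell_type = "Artifact",
      compartment = true_compartment_of(xy[, 1], xy[, 2], cfg),
      in_gc = FALSE))
  }

  n <- nrow(cells)
  is_art <- cells$cell_type == "Artifact"
  ki_prob <- ifelse(cells$in_gc & cells$cell_type == "BCL6+ FoB",
                    cfg$gc_ki67_prob, cfg$ki67_base_prob)
  mk <- draw_marker_matrix(n, ifelse(is_art, "Unknown", cells$cell_type),
                           cfg, ki_prob)
  intensity <- mk$intensity
  if (any(is_art)) {
    mu_hot <- cfg$log_mean_neg + cfg$marker_sep_sd * cfg$log_sd + 1.5
    for (m in setdiff(cfg$panel, "BCL6")) {
      intensity[is_art, m] <- exp(rnorm(sum(is_art), mu_hot, 0.3))
    }
    intensity[is_art, "BCL6"] <- exp(rnorm(sum(is_art),
      max(cfg$bcl6_mixture$log_means) + 1.5, 0.3))
    mk$bcl6_component[is_art] <- "artifact"
  }

  out <- bind_cols(
    tibble(cell_id = sprintf("%s_c%05d", sample_id, seq_len(n)),
           sample_id = sample_id, batch_id = batch_id,
           x_um = unname(cells$x_um), y_um = unname(cells$y_um)),
    as_tibble(intensity))
  truth <- tibble(
    cell_id = out$cell_id, sample_id = sample_id,
    true_phenotype = ifelse(is_art, "Excluded",
                            ifelse(cells$cell_type == "DP T", "Excluded",
                                   cells$cell_type)),
    true_compartment = cells$compartment,
    in_gc = cells$in_gc,
    bcl6_component = mk$bcl6_component,
    ki67_pos = mk$ki67_pos,
    artifact = is_art)
  validate_cell_table(out, cfg$panel)
  list(cells = set_panel(out, cfg$panel), truth = truth)
}

#' Simulate a labelled cohort
#'
#' Independent fields with deterministic per-sample child seeds, plus a
#' metadata table. Scale defaults mirror a two-arm case/control cohort.
#'
#' @param cfg A [synthetic_config()].
#' @param n_per_group Named integer vector, samples per group (default
#'   `c(pwMS = 28, control = 35)`).
#' @param seed Master seed (defaults to `cfg$seed`); the same seed
#'   reproduces the cohort exactly.
#' @return List with class `synthetic_cohort`: `cells` (all samples bound),
#'   `meta`, `truth` and `config`.
#' @export
simulate_cohort <- function(cfg = synthetic_config(),
                            n_per_group = c(pwMS = 28, control = 35),
                            seed = NULL) {
  if (is.null(names(n_per_group)) || any(n_per_group < 1)) {
    abort("n_per_group must be a named vector of counts >= 1")
  }
  seed <- seed %||% cfg$seed
  groups <- rep(names(n_per_group), n_per_group)
  ids <- sprintf("%s_%02d", groups, unlist(lapply(n_per_group, seq_len)))
  sims <- purrr::map(seq_along(ids), function(i) {
    simulate_sample(cfg, group = groups[i], sample_id = ids[i],
                    seed = child_seed(seed, "simulate", i))
  })
  cells <- bind_rows(purrr::map(sims, "cells"))
  meta <- tibble(sample_id = ids, group = groups, site = "axillary",
                 follicle_class = if (cfg$gc_present) "secondary" else "primary",
                 individual_id = ids)
  structure(list(cells = set_panel(cells, cfg$panel), meta = meta,
                 truth = bind_rows(purrr::map(sims, "truth")), config = cfg),
            class = "synthetic_cohort")
}

#' Ground-truth region polygons for the synthetic geometry
#'
#' Polygonises the analytic disks/annuli (256-gon rings, slightly
#' circumscribed so generated cells stay inside their compartment) into a
#' [region_set()] that can be written as GeoJSON or passed as manual
#' annotations.
#'
#' @inheritParams true_compartment_of
#' @param n_vertices Vertices per ring.
#' @return A `region_set` with provenance `"synthetic"`.
#' @export
synthetic_regions <- function(cfg, n_vertices = 256) {
  centre <- rep(cfg$field_radius_um, 2)
  # outer rings circumscribe their disk, holes are inscribed, so every
  # generated cell is contained in its compartment's polygon
  circ <- function(r, hole = FALSE) {
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)
    r_adj <- if (hole) r else r / cos(pi / n_vertices)
    cbind(centre[1] + r_adj * cos(th), centre[2] + r_adj * sin(th))
  }
  rr <- compartment_radii(cfg)
  polys <- tibble(
    polygon_id = c("follicle_1", "mantle_1", "tzone_1"),
    compartment = compartment_levels(),
    rings = list(list(circ(rr$follicle[2])),
                 list(circ(rr$mantle[2]), circ(rr$mantle[1], hole = TRUE)),
                 list(circ(rr$tzone[2]), circ(rr$tzone[1], hole = TRUE))))
  region_set(polys, provenance = "synthetic")
}
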