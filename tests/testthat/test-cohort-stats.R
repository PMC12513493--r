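make_comp_cells <- function(spec_tbl) {
  # spec_tbl: tibble(sample_id, compartment, phenotype, n)
  purrr::pmap(spec_tbl, function(sample_id, compartment, phenotype, n) {
    tibble::tibble(sample_id = sample_id, compartment = compartment,
                   phenotype = phenotype,
                   x_um = stats::runif(n, 0, 100),
                   y_um = stats::runif(n, 0, 100))
  }) %>% dplyr::bind_rows()
}

test_that("abundance computes counts, densities and proportions per scope", {
  cells <- make_comp_cells(tibble::tibble(
    sample_id = "s1", compartment = "follicle",
    phenotype = c("Tfh", "Th", "Unknown"), n = c(10, 30, 10)))
  areas <- tibble::tibble(compartment = "follicle", area_mm2 = 0.5)
  ab <- abundance(cells, areas = areas)
  tfh <- ab[ab$cell_type == "Tfh" & ab$scope == "follicle", ]
  expect_equal(tfh$n, 10)
  expect_equal(tfh$density_mm2, 20)        # 10 cells in 0.5 mm^2
  expect_equal(tfh$prop, 0.25)             # Unknown not in the denominator
  expect_false("Unknown" %in% ab$cell_type)

  # parent-lineage denominator: 10 Tfh among 40 Th-lineage cells
  ab2 <- abundance(cells, areas = areas, denominator = "lineage")
  expect_equal(ab2$prop[ab2$cell_type == "Tfh" & ab2$scope == "follicle"],
               0.25)
  # proportions over the partition sum to one under the default denominator
  sums <- ab %>% dplyr::group_by(scope) %>%
    dplyr::summarise(s = sum(prop), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("abundance densities recover the generative intensities", {
  cfg <- small_cfg(gc_present = FALSE, artifact_frac = 0, unknown_frac = 0)
  n_samples <- 6
  sims <- purrr::map(seq_len(n_samples),
                     ~simulate_sample(cfg, sample_id = sprintf("S%d", .x),
                                      seed = 400 + .x))
  cells <- dplyr::bind_rows(purrr::map(sims, "cells"))
  truth <- dplyr::bind_rows(purrr::map(sims, "truth"))
  cells$phenotype <- truth$true_phenotype
  cells$compartment <- truth$true_compartment
  ab <- abundance(cells, areas = synthetic_areas(cfg))
  for (tp in c("Naive B", "Th", "Tfh")) {
    got <- mean(ab$density_mm2[ab$cell_type == tp & ab$scope == "mantle"])
    lambda <- cfg$densities$per_mm2[cfg$densities$cell_type == tp &
                                      cfg$densities$compartment == "mantle"]
    area <- synthetic_areas(cfg)$area_mm2[2]
    se <- sqrt(lambda / (area * n_samples))  # Poisson SE of the mean density
    expect_lt(abs(got - lambda), 3 * se + 1e-9)
  }
})

test_that("Tfh-to-Tfr ratio pools all FOXP3+ subsets and flags empty denominators", {
  cells <- make_comp_cells(tibble::tibble(
    sample_id = c(rep("s1", 4), "s2"),
    compartment = "mantle",
    phenotype = c("Tfh", "Tfr", "PD-1+ Treg", "Treg", "Tfh"),
    n = c(10, 2, 2, 1, 4)))
  r <- tfh_tfr_ratio(cells, "mantle")
  expect_equal(r$ratio[r$sample_id == "s1"], 2)      # 10 / (2 + 2 + 1)
  expect_true(is.na(r$ratio[r$sample_id == "s2"]))   # no FOXP3+ cells
  expect_match(r$reason[r$sample_id == "s2"], "no FOXP3")
})

test_that("follicle-to-mantle ratio bases behave as documented", {
  cells <- make_comp_cells(tibble::tibble(
    sample_id = "s1",
    compartment = c("follicle", "follicle", "mantle", "mantle"),
    phenotype = c("Tfh", "Th", "Tfh", "Th"), n = c(6, 94, 3, 97)))
  areas <- tibble::tibble(compartment = c("follicle", "mantle"),
                          area_mm2 = c(0.2, 0.1))
  ab <- abundance(cells, areas = areas)
  fm <- follicle_mantle_ratio(ab, "Tfh", basis = "proportion")
  expect_equal(fm$ratio, 2)                          # 0.06 / 0.03

  # identical composition in both compartments: ratio 1 for every type
  eq <- make_comp_cells(tidyr::expand_grid(
    sample_id = "s1", compartment = c("follicle", "mantle"),
    phenotype = c("Tfh", "Th", "FoB")) %>% dplyr::mutate(n = 20))
  ab_eq <- abundance(eq, areas = areas)
  for (tp in c("Tfh", "Th", "FoB")) {
    expect_equal(follicle_mantle_ratio(ab_eq, tp)$ratio, 1)
  }

  # adding Unknown cells changes neither basis: Unknown is excluded from
  # the proportion denominator by the partition rule, and never counted
  # in densities
  with_unknown <- dplyr::bind_rows(cells, make_comp_cells(tibble::tibble(
    sample_id = "s1", compartment = "follicle", phenotype = "Unknown",
    n = 100)))
  ab_u <- abundance(with_unknown, areas = areas)
  expect_equal(follicle_mantle_ratio(ab_u, "Tfh", basis = "proportion")$ratio,
               follicle_mantle_ratio(ab, "Tfh", basis = "proportion")$ratio)
  expect_equal(follicle_mantle_ratio(ab_u, "Tfh", basis = "density")$ratio,
               follicle_mantle_ratio(ab, "Tfh", basis = "density")$ratio)
})

test_that("BH adjustment matches its defining examples and bounds", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(30)
  p <- stats::runif(50)
  out <- bh_adjust(p)
  expect_true(all(out >= p - 1e-15))
  expect_true(all(out <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("group comparisons: identity null, filtering and monotone invariance", {
  set.seed(31)
  vals <- stats::rnorm(12)
  tbl <- tibble::tibble(sample_id = sprintf("s%02d", 1:12),
                        metric = "density", scope = "whole",
                        cell_type = "Tfh", value = rep(vals[1:6], 2))
  meta <- tibble::tibble(sample_id = sprintf("s%02d", 1:12),
                         group = rep(c("g1", "g2"), each = 6))
  cmp <- compare_groups(tbl, meta, c("g1", "g2"))
  expect_equal(cmp$p, 1)
  expect_equal(cmp$p_adj, 1)

  # three-group metadata: only the requested groups enter
  meta3 <- tibble::tibble(sample_id = sprintf("s%02d", 1:12),
                          group = rep(c("g1", "g2", "g3"), each = 4))
  tbl3 <- dplyr::mutate(tbl, value = stats::rnorm(12))
  cmp3 <- compare_groups(tbl3, meta3, c("g1", "g3"))
  expect_equal(cmp3$n_g1, 4)
  expect_equal(cmp3$n_g2, 4)

  # Wilcoxon p is invariant under strictly monotone transforms
  cmp_raw <- compare_groups(tbl3, meta3, c("g1", "g2"))
  cmp_exp <- compare_groups(dplyr::mutate(tbl3, value = exp(value)),
                            meta3, c("g1", "g2"))
  expect_equal(cmp_raw$p, cmp_exp$p)

  expect_error(compare_groups(tbl, meta[-(1:5), ], c("g1", "g2")),
               "insufficient group size")
})

test_that("comparison tidiers summarise the object", {
  tbl <- tidyr::expand_grid(sample_id = sprintf("s%02d", 1:8),
                            metric = "density", scope = "whole",
                            cell_type = c("A", "B"))
  set.seed(32)
  tbl$value <- stats::rnorm(nrow(tbl))
  meta <- tibble::tibble(sample_id = sprintf("s%02d", 1:8),
                         group = rep(c("g1", "g2"), each = 4))
  cmp <- compare_groups(tbl, meta, c("g1", "g2"))
  expect_s3_class(tidy(cmp), "tbl_df")
  g <- glance(cmp)
  expect_equal(g$n_tests, 2)
  expect_equal(g$n_families, 1)
})
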