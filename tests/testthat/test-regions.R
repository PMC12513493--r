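test_that("polygon areas are exact for squares and closed-form for annuli", {
  rs <- region_set(tibble::tibble(
    polygon_id = "f1", compartment = "follicle",
    rings = list(list(square_ring(0, 0, 1000)))))
  expect_equal(rs$polygons$area_mm2, 1.0)
  expect_equal(compartment_areas(rs)$area_mm2, 1.0)

  # annulus outer 310, inner 250 -> pi (310^2 - 250^2) um^2 = 0.1056 mm^2
  rs2 <- region_set(tibble::tibble(
    polygon_id = "m1", compartment = "mantle",
    rings = list(list(circle_ring(0, 0, 310, n = 720),
                      circle_ring(0, 0, 250, n = 720)))))
  expect_equal(rs2$polygons$area_mm2, pi * (310^2 - 250^2) / 1e6,
               tolerance = 1e-4)

  # translation invariance
  shift <- function(r) sweep(r, 2, c(12345, -6789), "+")
  rs3 <- region_set(tibble::tibble(
    polygon_id = "m1", compartment = "mantle",
    rings = list(list(shift(circle_ring(0, 0, 310, n = 720)),
                      shift(circle_ring(0, 0, 250, n = 720))))))
  expect_equal(rs3$polygons$area_mm2, rs2$polygons$area_mm2)
})

test_that("region sets reject unknown labels and degenerate or crossing rings", {
  expect_error(region_set(tibble::tibble(
    polygon_id = "p", compartment = "medulla",
    rings = list(list(square_ring(0, 0, 10))))), "medulla")
  expect_error(region_set(tibble::tibble(
    polygon_id = "p", compartment = "follicle",
    rings = list(list(rbind(c(0, 0), c(1, 1)))))), "degenerate")
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 6))
  expect_error(region_set(tibble::tibble(
    polygon_id = "p", compartment = "follicle",
    rings = list(list(bowtie)))), "self-intersecting")
})

test_that("GeoJSON round-trips polygons, labels and areas", {
  rs <- synthetic_regions(small_cfg())
  path <- withr::local_tempfile(fileext = ".geojson")
  write_regions(rs, path)
  back <- read_regions(path)
  expect_equal(back$polygons$compartment, rs$polygons$compartment)
  expect_equal(back$polygons$area_mm2, rs$polygons$area_mm2)
  expect_equal(back$polygons$rings[[2]][[2]], rs$polygons$rings[[2]][[2]],
               ignore_attr = TRUE)

  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  gj$features[[1]]$properties$compartment <- "medulla"
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_regions(path), "medulla")
  gj$features[[1]]$properties$compartment <- NULL
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_regions(path), "no compartment label")
})

test_that("innermost polygon wins and matches a ray-casting oracle", {
  disk <- circle_ring(500, 500, 200)
  annulus_outer <- circle_ring(500, 500, 400)
  rs <- region_set(tibble::tibble(
    polygon_id = c("f", "m"), compartment = c("follicle", "mantle"),
    rings = list(list(disk), list(annulus_outer))))  # overlapping disks
  set.seed(8)
  pts <- tibble::tibble(sample_id = "s", x_um = stats::runif(400, 0, 1000),
                        y_um = stats::runif(400, 0, 1000))
  got <- assign_compartments(pts, rs)$compartment
  in_disk <- pip_oracle(list(disk), pts$x_um, pts$y_um)
  in_outer <- pip_oracle(list(annulus_outer), pts$x_um, pts$y_um)
  want <- ifelse(in_disk, "follicle", ifelse(in_outer, "mantle", "unassigned"))
  expect_equal(got, want)
  # effective mantle area subtracts the nested disk
  areas <- compartment_areas(rs)
  expect_equal(areas$area_mm2[areas$compartment == "mantle"],
               pi * (400^2 - 200^2) / 1e6, tolerance = 1e-3)
})

test_that("polygon assignment equals the oracle on synthetic fields with holes", {
  cfg <- small_cfg()
  sim <- simulate_sample(cfg, seed = 13)
  rs <- synthetic_regions(cfg)
  got <- assign_compartments(sim$cells, rs)$compartment
  sub <- seq(1, nrow(sim$cells), by = 3)
  want <- rep("unassigned", length(sub))
  for (i in seq_len(nrow(rs$polygons))) {
    inside <- pip_oracle(rs$polygons$rings[[i]],
                         sim$cells$x_um[sub], sim$cells$y_um[sub])
    # polygons are disjoint here, so no tie-breaking is needed
    want[inside] <- rs$polygons$compartment[i]
  }
  expect_equal(got[sub], want)
})

test_that("density-based annotation recovers the generative compartments", {
  cfg <- small_cfg()
  pc <- default_pipeline_config(cfg)
  sim <- simulate_sample(cfg, seed = 17)
  cells <- call_markers(sim$cells, pc$thresholds)
  rs <- auto_annotate(cells)
  expect_identical(rs$provenance, "auto")
  got <- assign_compartments(cells, rs)$compartment
  expect_gte(mean(got == sim$truth$true_compartment), 0.90)
})

test_that("a field without CD20+ cells is all T zone, with a warning", {
  cells <- tibble::tibble(sample_id = "s", x_um = c(0, 10), y_um = c(0, 5),
                          call_CD20 = FALSE, call_CD21 = FALSE,
                          call_CD4 = TRUE)
  expect_warning(rs <- auto_annotate(cells), "CD20")
  expect_true(all(assign_compartments(cells, rs)$compartment == "tzone"))
})

test_that("follicle classification needs both Ki67 fraction and a BCL6+ cluster", {
  cfg <- small_cfg()
  pc <- default_pipeline_config(cfg)
  run <- function(seed, gc) {
    cfg2 <- small_cfg(gc_present = gc)
    sim <- simulate_sample(cfg2, seed = seed)
    cells <- assign_phenotypes(add_gmm_calls(flag_artifacts(
      call_markers(sim$cells, pc$thresholds)), seed = 2))
    cells <- assign_compartments(cells, synthetic_regions(cfg2))
    classify_follicle(cells)
  }
  expect_equal(run(31, gc = TRUE), "secondary")
  expect_equal(run(32, gc = FALSE), "primary")

  # constructed: high Ki67 fraction but only 5 clustered BCL6+ B cells
  n <- 40
  cells <- tibble::tibble(
    sample_id = "s", x_um = stats::runif(n, 0, 100),
    y_um = stats::runif(n, 0, 100), compartment = "follicle",
    phenotype = rep(c("FoB", "BCL6+ FoB"), c(35, 5)),
    call_KI67 = rep(c(TRUE, FALSE), c(16, 24)),
    call_BCL6 = rep(c(FALSE, TRUE), c(35, 5)))
  expect_equal(classify_follicle(cells), "primary")

  empty <- dplyr::mutate(cells, compartment = "tzone")
  expect_warning(out <- classify_follicle(empty), "no B cells")
  expect_equal(out, "unknown")
})
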