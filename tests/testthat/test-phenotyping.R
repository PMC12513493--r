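panel2 <- c("CD3", "CD4")

test_that("threshold calls use strict inequality and anchor the rescale at 0.5", {
  cells <- tibble::tibble(cell_id = c("a", "b", "c"), sample_id = "s",
                          batch_id = "b1", x_um = 0, y_um = 0,
                          CD3 = c(10, 5, 2), CD4 = c(0, 6, 5))
  thr <- list(b1 = c(CD3 = 5, CD4 = 5))
  out <- call_markers(cells, thr, panel = panel2, gmm_markers = character(0))
  expect_equal(out$call_CD3, c(TRUE, FALSE, FALSE))  # exactly at threshold: negative
  expect_equal(out$call_CD4, c(FALSE, TRUE, FALSE))
  expect_gt(out$scaled_CD3[1], 0.5)
  expect_lt(out$scaled_CD3[3], 0.5)
  expect_equal(out$scaled_CD4[3], 0.5)
  expect_error(call_markers(cells, list(b1 = c(CD3 = 5)), panel = panel2,
                            gmm_markers = character(0)), "b1.*CD4")
})

test_that("batch-specific thresholds change calls exactly for straddled intensities", {
  set.seed(1)
  base <- tibble::tibble(cell_id = sprintf("c%d", 1:200), sample_id = "s",
                         x_um = 0, y_um = 0, CD3 = stats::runif(200, 0, 20),
                         CD4 = stats::runif(200, 0, 20))
  thr <- list(b1 = c(CD3 = 5, CD4 = 5), b2 = c(CD3 = 12, CD4 = 12))
  a <- call_markers(dplyr::mutate(base, batch_id = "b1"), thr, panel = panel2,
                    gmm_markers = character(0))
  b <- call_markers(dplyr::mutate(base, batch_id = "b2"), thr, panel = panel2,
                    gmm_markers = character(0))
  for (m in panel2) {
    straddled <- base[[m]] > 5 & base[[m]] <= 12
    expect_equal(a[[paste0("call_", m)]] != b[[paste0("call_", m)]],
                 straddled)
  }
})

test_that("GMM binning recovers well-separated components and ranks them", {
  set.seed(42)
  mu <- c(2, 4.4, 6.8, 9.2, 11.6)  # 6 log-sd apart at sd 0.4
  comp <- sample(1:5, 4000, replace = TRUE)
  x <- exp(stats::rnorm(4000, mu[comp], 0.4))
  fit <- fit_gmm_bins(x, seed = 7)
  expect_s3_class(fit, "gmm_binning")
  expect_equal(fit$labels,
               c("background", "negative", "low", "medium", "high"))
  acc <- mean(as.integer(fit$bin) == comp)
  expect_gte(acc, 0.99)
  expect_equal(fit$positive, fit$bin == "high")
  td <- tidy(fit)
  expect_equal(nrow(td), 5)
  expect_true(all(diff(td$log_mean) > 0))
})

test_that("GMM bins are invariant under positive rescaling of raw intensities", {
  set.seed(43)
  mu <- c(2, 4.5, 7, 9.5, 12)
  comp <- sample(1:5, 3000, replace = TRUE, prob = c(.4, .25, .15, .1, .1))
  x <- exp(stats::rnorm(3000, mu[comp], 0.5))
  f1 <- fit_gmm_bins(x, seed = 11)
  for (gain in c(0.5, 3, 40)) {
    f2 <- fit_gmm_bins(gain * x, seed = 11)
    expect_equal(as.character(f2$bin), as.character(f1$bin),
                 info = sprintf("gain %.1f", gain))
  }
})

test_that("component collapse keeps the bin partition total with few true components", {
  set.seed(44)
  x <- exp(c(stats::rnorm(1500, 2, 0.4), stats::rnorm(500, 8, 0.4)))
  fit <- fit_gmm_bins(x, seed = 3)
  expect_lte(fit$n_components, 5)
  expect_false(any(is.na(fit$bin)))
  expect_equal(tail(fit$labels, 1), "high")
  # "high" is the top-mean surviving component: every high cell lies in
  # the upper cluster
  expect_true(all(x[fit$bin == "high"] > 100))
})

test_that("degenerate GMM inputs error and small samples are skipped with Unknown calls", {
  expect_error(fit_gmm_bins(rep(5, 100)), "degenerate",
               class = "follicular_gmm_degenerate")
  expect_error(fit_gmm_bins(stats::runif(20)), "floor",
               class = "follicular_gmm_floor")

  cfg <- small_cfg()
  sim <- simulate_sample(cfg, seed = 5)
  small <- sim$cells[1:30, ]
  small$sample_id <- "tiny"
  both <- dplyr::bind_rows(sim$cells, small)
  out <- add_gmm_calls(both, marker = "BCL6", seed = 2)
  expect_equal(attr(out, "gmm_skipped"), "tiny")
  expect_true(all(is.na(out$call_BCL6[out$sample_id == "tiny"])))
  expect_false(anyNA(out$call_BCL6[out$sample_id != "tiny"]))
})

test_that("gating assigns the canonical subset labels", {
  # PD-1+BCL6+ Th cell is Tfh regardless of ICOS
  expect_equal(assign_phenotypes(calls_row(c("CD3", "CD4", "PD1", "BCL6")))$phenotype,
               "Tfh")
  expect_equal(assign_phenotypes(calls_row(c("CD3", "CD4", "PD1", "BCL6",
                                             "ICOS")))$phenotype, "Tfh")
  # CD3+CD4+CD8+ triple positives are excluded
  expect_equal(assign_phenotypes(calls_row(c("CD3", "CD4", "CD8")))$phenotype,
               "Excluded")
  # CD20+ CD21- CD27- BCL6- B cell is naive
  expect_equal(assign_phenotypes(calls_row("CD20"))$phenotype, "Naive B")
  # lineage-marker-dim cell is Unknown
  expect_equal(assign_phenotypes(calls_row(character(0)))$phenotype, "Unknown")
  # remaining subset identities
  expect_equal(assign_phenotypes(calls_row(c("CD3", "CD4", "PD1")))$phenotype,
               "Tfh-like")
  expect_equal(assign_phenotypes(calls_row(c("CD3", "CD4", "FOXP3", "PD1",
                                             "BCL6")))$phenotype, "Tfr")
  expect_equal(assign_phenotypes(calls_row(c("CD3", "CD8", "PD1", "BCL6")))$phenotype,
               "Tfc")
  expect_equal(assign_phenotypes(calls_row(c("CD20", "CD21")))$phenotype, "FoB")
  expect_equal(assign_phenotypes(calls_row(c("CD20", "CD27")))$phenotype, "MB")
})

test_that("phenotyping partitions every cell and conserves the count", {
  cfg <- small_cfg()
  sim <- simulate_sample(cfg, seed = 6)
  pc <- default_pipeline_config(cfg)
  cells <- assign_phenotypes(add_gmm_calls(flag_artifacts(
    call_markers(sim$cells, pc$thresholds)), seed = 2))
  expect_equal(nrow(cells), nrow(sim$cells))
  expect_false(anyNA(cells$phenotype))
  known <- c(unique(default_densities()$cell_type), "Unknown", "Excluded",
             "Th", "Treg", "Tc", "B")
  expect_true(all(cells$phenotype %in% known))
})

test_that("broadband-bright artifacts are flagged and benign cells are not", {
  cfg <- small_cfg()
  sim <- simulate_sample(cfg, seed = 7)
  flagged <- flag_artifacts(sim$cells)
  truth <- sim$truth$artifact
  expect_gte(mean(flagged$artifact[truth]), 0.95)
  expect_lte(mean(flagged$artifact[!truth]), 0.01)

  # an all-zero cell is never above a positive quantile
  zero <- sim$cells[1, ]
  zero[, cfg$panel] <- 0
  zero$cell_id <- "zero"
  with_zero <- flag_artifacts(dplyr::bind_rows(sim$cells, zero))
  expect_false(with_zero$artifact[with_zero$cell_id == "zero"])

  # a vacuous rule (100th percentile) flags nothing
  none <- flag_artifacts(sim$cells, quantile = 1)
  expect_equal(sum(none$artifact), 0)
})

test_that("QC filter applies the strict 30 percent rule and per-individual choice", {
  mk <- function(id, unknown_frac, n = 100) {
    tibble::tibble(sample_id = id, cell_id = sprintf("%s_%d", id, 1:n),
                   phenotype = rep(c("Unknown", "Th"),
                                   c(round(unknown_frac * n),
                                     n - round(unknown_frac * n))))
  }
  cells <- dplyr::bind_rows(mk("over", 0.31), mk("at", 0.30), mk("under", 0.05))
  qc <- qc_filter_samples(cells)
  expect_setequal(unique(qc$cells$sample_id), c("at", "under"))
  expect_match(qc$report$reason[qc$report$sample_id == "over"], "> 0.30")

  meta <- tibble::tibble(sample_id = c("i1_a", "i1_b", "i2_a"), group = "g",
                         individual_id = c("i1", "i1", "i2"))
  cells2 <- dplyr::bind_rows(mk("i1_a", 0.12), mk("i1_b", 0.05), mk("i2_a", 0.2))
  qc2 <- qc_filter_samples(cells2, meta = meta)
  expect_setequal(unique(qc2$cells$sample_id), c("i1_b", "i2_a"))

  # idempotence
  qc3 <- qc_filter_samples(qc2$cells, meta = meta)
  expect_identical(sort(unique(qc3$cells$sample_id)),
                   sort(unique(qc2$cells$sample_id)))
  expect_true(all(qc3$report$kept))
})
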