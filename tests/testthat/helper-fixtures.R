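# Shared fixtures: all synthetic, built in code at test time.

# A reduced-density configuration for fast unit tests (the full defaults
# are exercised in test-acceptance.R).
small_cfg <- function(...) {
  d <- default_densities()
  d$per_mm2 <- d$per_mm2 * 0.4
  synthetic_config(densities = d,
                   gc_densities = dplyr::tibble(
                     cell_type = c("BCL6+ FoB", "Tfh"), per_mm2 = c(800, 120)),
                   ...)
}

# One-row call table for gating unit tests: markers given in `pos` are
# called positive, everything else negative.
calls_row <- function(pos) {
  markers <- c("CD3", "CD4", "CD8", "FOXP3", "CD20", "CD21", "CD27",
               "PD1", "ICOS", "BCL6", "KI67")
  df <- tibble::tibble(cell_id = "c1", sample_id = "s1",
                       x_um = 0, y_um = 0)
  for (m in markers) df[[paste0("call_", m)]] <- m %in% pos
  df
}

# Independent even-odd (ray casting) point-in-polygon oracle, written
# separately from the implementation path.
pip_oracle <- function(rings, px, py) {
  in_ring <- function(r, x, y) {
    n <- nrow(r); j <- n; inside <- FALSE
    for (i in seq_len(n)) {
      xi <- r[i, 1]; yi <- r[i, 2]; xj <- r[j, 1]; yj <- r[j, 2]
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
      j <- i
    }
    inside
  }
  vapply(seq_along(px), function(i) {
    crossings <- vapply(rings, function(r) in_ring(r, px[i], py[i]), logical(1))
    sum(crossings) %% 2 == 1
  }, logical(1))
}

square_ring <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

circle_ring <- function(cx, cy, r, n = 128) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Uniform CSR field with iid labels, as a minimal phenotyped cell table.
csr_field <- function(n, labels, sample_id = "f", width = 1000) {
  tibble::tibble(sample_id = sample_id,
                 x_um = stats::runif(n, 0, width),
                 y_um = stats::runif(n, 0, width),
                 phenotype = labels)
}
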