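# Internal helpers shared across modules.

# Deterministic child seed for (stage, index), derived from the master seed.
# Kept strictly below 2^31 so it is always a valid R integer.
child_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage)) %% 10000L
  as.integer((as.double(seed) * 48271 + h * 2633 + as.double(index) * 7919) %%
               2147483647)
}

compartment_levels <- function() c("follicle", "mantle", "tzone")

assert_columns <- function(df, cols, where = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s", where,
                  paste(missing, collapse = ", ")),
          class = "follicular_schema_error")
  }
  invisible(df)
}

call_col <- function(marker) paste0("call_", marker)
scaled_col <- function(marker) paste0("scaled_", marker)
bin_col <- function(marker) paste0("bin_", marker)

# Panel resolution: explicit argument wins, else the attribute stamped by
# read_cell_table()/simulate_sample().
resolve_panel <- function(cells, panel = NULL) {
  panel <- panel %||% attr(cells, "panel")
  if (is.null(panel)) {
    abort(paste0("no marker panel available: pass `panel` or use a table ",
                 "created by read_cell_table()/simulate_sample()"))
  }
  panel
}

set_panel <- function(cells, panel) {
  attr(cells, "panel") <- panel
  cells
}

# Shoelace area of a single ring (matrix with columns x, y), in the input
# units squared. Sign follows orientation; callers take abs().
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Area (units^2) of a polygon given as list of rings (outer first, then holes).
polygon_area_units <- function(rings) {
  a <- abs(ring_area(rings[[1]]))
  if (length(rings) > 1) {
    a <- a - sum(vapply(rings[-1], function(r) abs(ring_area(r)), numeric(1)))
  }
  max(a, 0)
}

um2_to_mm2 <- function(x) x / 1e6

# Convex hull area of a point set in mm^2 (fallback tissue area when no
# region polygons are available).
hull_area_mm2 <- function(x, y) {
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  um2_to_mm2(abs(ring_area(cbind(x[h], y[h]))))
}
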