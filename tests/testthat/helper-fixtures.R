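# Shared fixtures: tiny rasters and scenes built in code.

tiny_raster <- function(values, nrow = 2, ncol = 2, ...) {
  grid_raster(matrix(values, nrow, ncol), ...)
}

# A minimal covariate stack on a 2x2 grid:
#   density 50/30/10/0, heights 9/4.5/3/0, types MF/SF/SF/NONE
tiny_stack <- function() {
  list(
    density = tiny_raster(c(50, 30, 10, 0)),
    height = tiny_raster(c(9, 4.5, 3, 0)),
    types = tiny_raster(c(TYPE_CODES[["MF"]], TYPE_CODES[["SF"]],
                          TYPE_CODES[["SF"]], TYPE_CODES[["NONE"]]))
  )
}

# One-level hierarchy from an explicit label matrix + census vector.
manual_level <- function(labels_mat, census, cell_size = 10) {
  list(labels = grid_raster(labels_mat, cell_size = cell_size),
       n_zones = length(census), census = census,
       area_km2 = as.numeric(table(factor(labels_mat,
                                          levels = seq_along(census)))) *
         (cell_size / 1000)^2)
}

# Small default scene used across tests (cached per session).
small_scene <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1, ...) {
    key <- paste0("s", seed, "_", paste(deparse(list(...)), collapse = ""))
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_landscape(
        scene_config(grid_shape = c(64, 64),
                     n_zones_per_level = c(1, 4, 16), seed = seed, ...))
    cache[[key]]
  }
})

# Independent brute-force oracle for dasymetric redistribution: explicit
# cell-by-cell loop over zones (no vectorised sharing with the package).
oracle_redistribute <- function(labels_mat, weights_mat, census) {
  out <- matrix(0, nrow(labels_mat), ncol(labels_mat))
  for (z in seq_along(census)) {
    wsum <- 0
    for (i in seq_len(nrow(labels_mat)))
      for (j in seq_len(ncol(labels_mat)))
        if (labels_mat[i, j] == z) wsum <- wsum + weights_mat[i, j]
    for (i in seq_len(nrow(labels_mat)))
      for (j in seq_len(ncol(labels_mat)))
        if (labels_mat[i, j] == z && wsum > 0)
          out[i, j] <- weights_mat[i, j] * census[z] / wsum
  }
  out
}

# Independent oracle for zonal aggregation: dictionary accumulation.
oracle_aggregate <- function(pop_mat, labels_mat, n_zones) {
  acc <- numeric(n_zones)
  for (i in seq_len(nrow(pop_mat)))
    for (j in seq_len(ncol(pop_mat)))
      acc[labels_mat[i, j]] <- acc[labels_mat[i, j]] + pop_mat[i, j]
  acc
}
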