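#' Lightweight single-band raster on a regular planar grid
#'
#' A `grid_raster` is a numeric matrix (rows = northings, row 1 is the
#' northern edge; columns = eastings) together with the georeferencing
#' metadata needed for alignment checks and text serialisation: the
#' coordinate of the lower-left corner, the cell size in metres, and a free
#' CRS note. A projected, metre-unit CRS is assumed throughout; cells are
#' square.
#'
#' @param values numeric matrix of cell values.
#' @param cell_size cell edge length in metres (default 10, i.e. 100 m2
#'   cells so that one percent of building density equals 1 m2).
#' @param xll,yll coordinates of the lower-left grid corner in metres.
#' @param crs free-text CRS note; must describe a projected metre-unit
#'   system.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, cell_size = 10, xll = 0, yll = 0,
                        crs = "local-metric") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll), crs = as.character(crs)),
    class = "grid_raster"
  )
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<grid_raster> %d x %d cells, %g m resolution (%s)\n",
              d[1], d[2], x$cell_size, x$crs))
  cat(sprintf("  origin (xll, yll): (%g, %g)\n", x$xll, x$yll))
  if (length(v))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g\n",
                min(v), mean(v), max(v)))
  invisible(x)
}

#' Grid metadata equality used by every multi-layer operation
#'
#' Two rasters are aligned when they share shape, cell size, origin and CRS
#' note. Operations combining layers call [check_aligned()] and fail with an
#' alignment error naming both grids when they differ.
#'
#' @param a,b `grid_raster` objects.
#' @return `TRUE` invisibly, or an error.
#' @export
check_aligned <- function(a, b) {
  stopifnot(inherits(a, "grid_raster"), inherits(b, "grid_raster"))
  describe <- function(r)
    sprintf("[%dx%d @ %gm, origin (%g,%g), crs '%s']",
            nrow(r$values), ncol(r$values), r$cell_size, r$xll, r$yll, r$crs)
  same <- identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$xll, b$xll)) && isTRUE(all.equal(a$yll, b$yll)) &&
    identical(a$crs, b$crs)
  if (!same)
    stop("raster alignment error: grids differ: ", describe(a), " vs ",
         describe(b), call. = FALSE)
  invisible(TRUE)
}

#' @rdname check_aligned
#' @param ... `grid_raster` objects checked pairwise against the first.
#' @export
check_aligned_all <- function(...) {
  rs <- list(...)
  for (i in seq_along(rs)[-1]) check_aligned(rs[[1]], rs[[i]])
  invisible(TRUE)
}

## Build a raster sharing r's grid metadata but holding new values.
raster_like <- function(r, values) {
  grid_raster(matrix(values, nrow = nrow(r$values), ncol = ncol(r$values)),
              cell_size = r$cell_size, xll = r$xll, yll = r$yll, crs = r$crs)
}

#' Building type codes
#'
#' Integer codes used in type rasters: 0 = NONE (no mapped building),
#' 1 = SF (single-family residential), 2 = MF (multi-family residential),
#' 3 = IC (industrial/commercial), 4 = LS (lightweight structure). Only SF
#' and MF carry de jure population.
#'
#' @format named integer vector.
#' @export
TYPE_CODES <- c(NONE = 0L, SF = 1L, MF = 2L, IC = 3L, LS = 4L)

## Validate a type raster's codes; unknown codes are a data error.
check_type_codes <- function(types) {
  v <- types$values
  bad <- setdiff(unique(as.vector(v)), as.numeric(TYPE_CODES))
  if (length(bad))
    stop("data error: unknown building type code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
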