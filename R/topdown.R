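#' Gridded population result
#'
#' A `pop_grid` is a [grid_raster()] of persons per cell with provenance:
#' the estimation method tag and, for top-down products, the census input
#' level. Population is kept real-valued (volume-preserving dasymetric
#' convention); use [integerize_population()] for integer export.
#'
#' @param raster `grid_raster` of persons per cell (nonnegative, finite).
#' @param method method tag, e.g. `"WD-VOLADJ"` or `"BU-LFA"`.
#' @param input_level census input level name, or NA for bottom-up.
#' @return object of class `c("pop_grid", "grid_raster")`.
#' @export
pop_grid <- function(raster, method = "unknown", input_level = NA) {
  stopifnot(inherits(raster, "grid_raster"))
  v <- raster$values
  if (any(!is.finite(v)) || any(v < 0))
    stop("data error: population grid must be finite and nonnegative",
         call. = FALSE)
  raster$method <- method
  raster$input_level <- input_level
  class(raster) <- c("pop_grid", "grid_raster")
  raster
}

#' @export
print.pop_grid <- function(x, ...) {
  cat(sprintf("<pop_grid> method %s%s\n", x$method,
              if (!is.na(x$input_level))
                paste0(", census input level ", x$input_level) else ""))
  cat(sprintf("  %d x %d cells at %g m, total population %.2f\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              sum(x$values)))
  cat(sprintf("  populated cells: %d (max %.2f persons/cell)\n",
              sum(x$values > 0), max(x$values)))
  invisible(x)
}

#' @export
summary.pop_grid <- function(object, ...) {
  v <- object$values
  out <- list(method = object$method, input_level = object$input_level,
              total = sum(v), cells = length(v),
              populated_cells = sum(v > 0),
              per_cell = summary(as.vector(v[v > 0])))
  class(out) <- "summary.pop_grid"
  out
}

#' @export
print.summary.pop_grid <- function(x, ...) {
  cat(sprintf("Population grid (%s): total %.2f persons over %d of %d cells\n",
              x$method, x$total, x$populated_cells, x$cells))
  cat("Persons per populated cell:\n")
  print(x$per_cell)
  invisible(x)
}

#' @export
plot.pop_grid <- function(x, main = NULL, ...) {
  plot_grid_values(x, main = main %||% sprintf("Population (%s)", x$method),
                   ...)
}

#' Dasymetric redistribution of zonal census counts
#'
#' Redistributes each zone's census population to its cells proportionally
#' to a nonnegative weight layer:
#' \deqn{pop_{ij} = w_{ij} \cdot pop_{total}(z) / \sum_{(i,j) \in z} w_{ij}.}
#' With binary weights this is binary dasymetric mapping (every admissible
#' cell gets an equal share); with continuous weights it is weighted
#' dasymetric mapping. The scheme is volume-preserving: each zone's cell sum
#' equals its census count, and scaling all weights by a positive constant
#' leaves the result unchanged.
#'
#' Zones with positive census but all-zero weights cannot absorb their
#' population through the weights. Under the default `"uniform"` fallback
#' their census is spread equally over all their cells and a warning names
#' them; under `"strict"` this is an error.
#'
#' @param level one level of a [zone_hierarchy] (list with `labels`,
#'   `census`), or a `zone_hierarchy` plus `which_level`.
#' @param weights nonnegative weight `grid_raster` from [make_weights()].
#' @param fallback `"uniform"` or `"strict"`.
#' @param which_level level name/index when `level` is a full hierarchy.
#' @return a `pop_grid`.
#' @export
redistribute <- function(level, weights, fallback = c("uniform", "strict"),
                         which_level = NULL) {
  fallback <- match.arg(fallback)
  if (inherits(level, "zone_hierarchy")) {
    if (is.null(which_level))
      stop("invalid parameter: give `which_level` with a full hierarchy",
           call. = FALSE)
    level_name <- if (is.character(which_level)) which_level
                  else names(level$levels)[which_level]
    level <- get_level(level, which_level)
  } else level_name <- attr(level, "name") %||% NA
  check_aligned(level$labels, weights)
  w <- as.vector(weights$values)
  if (any(!is.finite(w)) || any(w < 0))
    stop("data error: weights must be finite and nonnegative", call. = FALSE)
  z <- as.integer(level$labels$values)
  census <- level$census
  if (anyNA(census))
    stop("data error: census undefined for some zones at this level",
         call. = FALSE)
  if (any(census < 0))
    stop("data error: negative census count", call. = FALSE)
  nz <- level$n_zones
  wsum <- rowsum(w, z)[, 1]
  wsum_full <- numeric(nz)
  wsum_full[as.integer(rownames(rowsum(w, z)))] <- wsum
  empty <- which(wsum_full == 0 & census > 0)
  if (length(empty)) {
    if (fallback == "strict")
      stop("zone(s) with positive census but all-zero weights: ",
           paste(empty, collapse = ", "), call. = FALSE)
    warning("uniform fallback applied to zone(s) with positive census but ",
            "all-zero weights: ", paste(empty, collapse = ", "),
            call. = FALSE)
    w[z %in% empty] <- 1
    wsum_full[empty] <- rowsum(w[z %in% empty],
                               z[z %in% empty])[, 1]
  }
  factor <- ifelse(wsum_full > 0, census / wsum_full, 0)
  pop <- w * factor[z]
  pop_grid(raster_like(weights, pop),
           method = attr(weights, "method") %||% "custom-weights",
           input_level = level_name)
}

#' Best-product configuration
#'
#' The most accurate top-down product: the finest available census level
#' (municipal analogue) redistributed with adjusted residential building
#' volume weights (WD-VOLADJ).
#'
#' @param zones a [zone_hierarchy] with census filled at the finest level.
#' @param covariates covariate stack with `density`, `height`, `types`.
#' @param mf_factor MF volume adjustment factor (default 1.6).
#' @param ... passed to [redistribute()].
#' @return a `pop_grid`.
#' @export
best_product <- function(zones, covariates, mf_factor = 1.6, ...) {
  finest <- length(zones$levels)
  w <- make_weights("WD-VOLADJ", covariates, mf_factor = mf_factor)
  redistribute(zones, w, which_level = finest, ...)
}

#' Integer population export
#'
#' Largest-remainder integerisation of a real-valued population grid. With
#' `zones`/`which_level` the rounding is balanced within each zone (zone
#' totals become the rounded zone sums); otherwise it is balanced globally.
#' Every cell moves by less than one person.
#'
#' @param pop a `pop_grid`.
#' @param zones optional [zone_hierarchy].
#' @param which_level level used for per-zone balancing.
#' @return a `pop_grid` of integer counts.
#' @export
integerize_population <- function(pop, zones = NULL, which_level = NULL) {
  v <- as.vector(pop$values)
  if (is.null(zones)) {
    out <- hamilton_round(v)
  } else {
    lv <- get_level(zones, which_level %||% length(zones$levels))
    z <- as.integer(lv$labels$values)
    out <- numeric(length(v))
    for (zz in unique(z)) {
      i <- which(z == zz)
      out[i] <- hamilton_round(v[i])
    }
  }
  pop_grid(raster_like(pop, out), method = paste0(pop$method, "-INT"),
           input_level = pop$input_level)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
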