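#' Nested administrative zone hierarchies
#'
#' A `zone_hierarchy` is an ordered list of levels, coarse to fine. Each
#' level holds a label raster assigning every cell to exactly one zone, a
#' census population per zone (filled by the landscape generator or read
#' from a census table) and zone areas in km2. Finer levels are exact
#' refinements of coarser ones: a child zone never straddles a parent
#' boundary, so aggregating a finer census reproduces every coarser census
#' exactly. The default four levels emulate a national unit on top of a
#' state / district / municipality nesting.
#'
#' @name zone_hierarchy
NULL

## Run code with a transient RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

## Largest-remainder (Hamilton) integerisation of a nonnegative vector to a
## nonnegative integer target total. Each element moves by less than 1.
hamilton_round <- function(x, target = round(sum(x))) {
  stopifnot(all(x >= 0), target >= 0)
  lo <- floor(x)
  short <- as.integer(target - sum(lo))
  if (short < 0) { # target below floor sum: take from smallest remainders
    ord <- order(x - lo, -x)
    take <- ord[seq_len(min(-short, sum(lo > 0)))]
    lo[take] <- pmax(lo[take] - 1L, 0)
    # degenerate: if still above target (zeros everywhere), leave as is
  } else if (short > 0) {
    ord <- order(x - lo, x, decreasing = TRUE)
    lo[ord[seq_len(short)]] <- lo[ord[seq_len(short)]] + 1
  }
  lo
}

#' Partition a grid into nested zones
#'
#' Builds a zone hierarchy by recursive spatial splitting of the cell grid:
#' each parent zone is divided among its children with alternating-axis,
#' jittered median splits, giving contiguous, irregular, exactly nested
#' zones. Child counts are apportioned to parents proportionally to parent
#' cell counts (largest remainder, at least one child each).
#'
#' @param grid_shape integer vector `c(rows, cols)`.
#' @param counts zones per level, strictly increasing, e.g. `c(1, 4, 16, 64)`.
#' @param seed integer seed for the split-point jitter.
#' @param cell_size cell edge length in metres (used for zone areas).
#' @param level_names optional level names; defaults to `L1`, `L2`, ...
#' @return a `zone_hierarchy`: list of levels, each with elements
#'   `labels` (`grid_raster` of integer zone ids 1..n), `census` (NA until
#'   filled), `area_km2`, and `n_zones`.
#' @export
partition_zones <- function(grid_shape, counts, seed = 1, cell_size = 10,
                            level_names = NULL) {
  counts <- as.integer(counts)
  if (length(counts) < 1L || any(is.na(counts)) || any(counts < 1L))
    stop("invalid configuration: zone counts must all be >= 1", call. = FALSE)
  if (length(counts) > 1L && any(diff(counts) <= 0L))
    stop("invalid configuration: zone counts must be strictly increasing ",
         "across levels", call. = FALSE)
  rows <- as.integer(grid_shape[1]); cols <- as.integer(grid_shape[2])
  n_cells <- rows * cols
  if (max(counts) > n_cells)
    stop("invalid configuration: more zones than cells (",
         max(counts), " > ", n_cells, ")", call. = FALSE)
  if (is.null(level_names)) level_names <- sprintf("L%d", seq_along(counts))

  ## cell coordinates, column-major to match matrix indexing
  ri <- rep(seq_len(rows), times = cols)
  ci <- rep(seq_len(cols), each = rows)

  ## split one zone's cell indices into k contiguous parts
  split_k <- function(idx, k, depth) {
    if (k == 1L) return(list(idx))
    k1 <- k %/% 2L; k2 <- k - k1
    axis <- if (depth %% 2L == 0L) ri[idx] else ci[idx]
    tie <- if (depth %% 2L == 0L) ci[idx] else ri[idx]
    ord <- order(axis, tie)
    n <- length(idx)
    jit <- stats::runif(1, -0.12, 0.12)
    cut <- round(n * (k1 / k) * (1 + jit))
    cut <- min(max(cut, k1), n - k2)  # both sides must host their children
    a <- idx[ord[seq_len(cut)]]
    b <- idx[ord[(cut + 1L):n]]
    c(split_k(a, k1, depth + 1L), split_k(b, k2, depth + 1L))
  }

  levels <- vector("list", length(counts))
  names(levels) <- level_names
  with_seed(seed, {
    parent_groups <- list(seq_len(n_cells))  # level 0: whole grid
    depth <- 0L
    for (l in seq_along(counts)) {
      n_par <- length(parent_groups)
      sizes <- lengths(parent_groups)
      ## children per parent: proportional, >= 1 each
      extra <- counts[l] - n_par
      kids <- rep(1L, n_par)
      if (extra > 0L)
        kids <- kids + hamilton_round(extra * sizes / sum(sizes), extra)
      groups <- list()
      for (p in seq_len(n_par))
        groups <- c(groups, split_k(parent_groups[[p]], kids[p], depth))
      depth <- depth + 1L
      lab <- integer(n_cells)
      for (z in seq_along(groups)) lab[groups[[z]]] <- z
      labels <- grid_raster(matrix(as.numeric(lab), rows, cols),
                            cell_size = cell_size)
      area <- as.numeric(table(factor(lab, levels = seq_along(groups)))) *
        (cell_size / 1000)^2
      levels[[l]] <- list(labels = labels, n_zones = length(groups),
                          census = rep(NA_real_, length(groups)),
                          area_km2 = area)
      parent_groups <- groups
    }
  })
  structure(list(levels = levels, cell_size = cell_size,
                 total_area_km2 = n_cells * (cell_size / 1000)^2),
            class = "zone_hierarchy")
}

#' @export
print.zone_hierarchy <- function(x, ...) {
  cat(sprintf("<zone_hierarchy> %d level(s), total area %.2f km2\n",
              length(x$levels), x$total_area_km2))
  for (nm in names(x$levels)) {
    lv <- x$levels[[nm]]
    filled <- !all(is.na(lv$census))
    cat(sprintf("  %-12s %5d zones, ASR %.3f km, census %s\n", nm,
                lv$n_zones, asr(x$total_area_km2, lv$n_zones),
                if (filled) sprintf("total %.0f", sum(lv$census)) else "unset"))
  }
  invisible(x)
}

## Fill every level's census by exact aggregation of a truth grid.
fill_census <- function(zones, truth) {
  for (nm in names(zones$levels)) {
    lv <- zones$levels[[nm]]
    zones$levels[[nm]]$census <-
      aggregate_to_zones(truth, lv)
  }
  zones
}

## Fetch one level by name or index, with a clear error.
get_level <- function(zones, level) {
  stopifnot(inherits(zones, "zone_hierarchy"))
  if (is.numeric(level)) {
    if (level < 1 || level > length(zones$levels))
      stop("invalid parameter: no zone level ", level, call. = FALSE)
    return(zones$levels[[level]])
  }
  if (!level %in% names(zones$levels))
    stop("invalid parameter: no zone level named '", level, "'", call. = FALSE)
  zones$levels[[level]]
}
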