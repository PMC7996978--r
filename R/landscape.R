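#' Configuration of a synthetic landscape
#'
#' Describes the statistical structure of a generated scene: settlement
#' patches on an urban-rural gradient, building density in [0, 100] percent
#' concentrated in those patches, building height positively correlated
#' with density, residential types following the density gradient
#' (multi-family in dense cores, single-family at the fringes), separate
#' industrial/commercial patches, scattered lightweight structures, a
#' nested zone hierarchy, and a ground-truth population produced by the
#' floor-area forward model with multiplicative lognormal noise.
#'
#' @param grid_shape `c(rows, cols)` cells (default 128 x 128).
#' @param cell_size metres per cell edge (default 10).
#' @param n_settlement_seeds number of settlement patch centres (default 12).
#' @param urban_fraction share of cells carrying buildings (default 0.2).
#' @param height_density_corr target Pearson correlation of height and
#'   density over built cells, in (0, 1) (default 0.7).
#' @param type_rules list: `mf_min` density percent at or above which a
#'   residential cell is multi-family (default 60); `ls_frac` share of
#'   low-density built cells turned into lightweight structures (default
#'   0.03); `ic_seed_frac` share of settlement seeds that are
#'   industrial/commercial patches (default 0.2).
#' @param n_zones_per_level strictly increasing zone counts; the default
#'   `c(1, 4, 16, 64)` emulates a national unit over state / district /
#'   municipality levels.
#' @param lfa_table living floor area per capita, data frame with columns
#'   `region`, `type`, `lfa_per_cap_m2`; `NULL` generates a regional table
#'   around 45 m2/person (SF) and 35 m2/person (MF).
#' @param noise_sd lognormal sigma of the multiplicative truth noise
#'   (default 0.25; 0 gives the deterministic forward model).
#' @param populate_all_zones if `TRUE` (default) every leaf zone lacking a
#'   residential building cell above the 25 percent density threshold
#'   receives a small single-family hamlet, mirroring the fact that
#'   administrative census units are drawn around settlements and
#'   essentially never have zero population.
#' @param floor_model_ a [floor_model()] used by the forward model.
#' @param region_level hierarchy level used as LFA/cap regionalisation;
#'   default: coarsest level with more than one zone.
#' @param seed integer RNG seed.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(grid_shape = c(128, 128), cell_size = 10,
                         n_settlement_seeds = 12, urban_fraction = 0.2,
                         height_density_corr = 0.7,
                         type_rules = list(mf_min = 60, ls_frac = 0.03,
                                           ic_seed_frac = 0.2),
                         n_zones_per_level = c(1, 4, 16, 64),
                         lfa_table = NULL, noise_sd = 0.25,
                         populate_all_zones = TRUE,
                         floor_model_ = floor_model(),
                         region_level = NULL, seed = 1) {
  cfg <- list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
              n_settlement_seeds = as.integer(n_settlement_seeds),
              urban_fraction = urban_fraction,
              height_density_corr = height_density_corr,
              type_rules = utils::modifyList(
                list(mf_min = 60, ls_frac = 0.03, ic_seed_frac = 0.2),
                type_rules),
              n_zones_per_level = as.integer(n_zones_per_level),
              lfa_table = lfa_table, noise_sd = noise_sd,
              populate_all_zones = isTRUE(populate_all_zones),
              floor_model = floor_model_, region_level = region_level,
              seed = as.integer(seed))
  validate_scene_config(cfg)
  class(cfg) <- "scene_config"
  cfg
}

validate_scene_config <- function(cfg) {
  n_cells <- prod(cfg$grid_shape)
  if (length(cfg$grid_shape) != 2L || any(cfg$grid_shape < 4L))
    stop("invalid configuration: grid_shape must be two values >= 4",
         call. = FALSE)
  if (cfg$cell_size <= 0)
    stop("invalid configuration: cell_size must be positive", call. = FALSE)
  if (cfg$n_settlement_seeds < 1L)
    stop("invalid configuration: need at least one settlement seed",
         call. = FALSE)
  if (cfg$urban_fraction <= 0 || cfg$urban_fraction >= 1)
    stop("invalid configuration: urban_fraction must be in (0, 1)",
         call. = FALSE)
  if (cfg$height_density_corr <= 0 || cfg$height_density_corr >= 1)
    stop("invalid configuration: height_density_corr must be in (0, 1)",
         call. = FALSE)
  counts <- cfg$n_zones_per_level
  if (any(counts < 1L) ||
      (length(counts) > 1L && any(diff(counts) <= 0L)))
    stop("invalid configuration: n_zones_per_level must be >= 1 and ",
         "strictly increasing", call. = FALSE)
  if (max(counts) > n_cells)
    stop("invalid configuration: more zones than cells", call. = FALSE)
  if (cfg$noise_sd < 0)
    stop("invalid configuration: noise_sd must be >= 0", call. = FALSE)
  invisible(TRUE)
}

## Default LFA/cap table: SF around 45 m2/person, MF around 35, with
## +/- 15% regional variation (deterministic in the region index so the
## table does not consume scene RNG draws).
default_lfa_table <- function(n_regions) {
  r <- seq_len(n_regions)
  wiggle <- 1 + 0.15 * sin(2.3 * r)  # fixed, smooth regional variation
  rbind(
    data.frame(region = r, type = "SF", lfa_per_cap_m2 = 45 * wiggle),
    data.frame(region = r, type = "MF", lfa_per_cap_m2 = 35 * wiggle)
  )
}

## Mean filter over a disc of `radius_m`, matrix edge-padded by
## renormalising over in-grid neighbours.
disc_smooth <- function(m, cell_size, radius_m = 50) {
  r_cells <- floor(radius_m / cell_size)
  if (r_cells < 1L) return(m)
  offs <- expand.grid(dr = -r_cells:r_cells, dc = -r_cells:r_cells)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r_cells^2, ]
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    acc[rs, cs] <- acc[rs, cs] + m[rs + dr, cs + dc]
    cnt[rs, cs] <- cnt[rs, cs] + 1
  }
  acc / cnt
}

#' Generate a synthetic landscape with known ground truth
#'
#' Produces co-registered covariate rasters (building density, height,
#' type), a nested zone hierarchy with census tables, a region map, an
#' LFA/cap table, and a per-cell ground-truth population. The truth is the
#' floor-area forward model itself — floors from height, living floor area
#' from floors and density, divided by the regional LFA/cap of the cell's
#' type — times multiplicative lognormal noise, integerised per leaf zone
#' by largest-remainder rounding so every zone census is exactly the sum of
#' the integer truth and every cell stays within one person of the raw
#' model. Industrial/commercial and lightweight-structure cells carry zero
#' truth population (de jure convention).
#'
#' @param config a [scene_config()].
#' @return object of class `synth_scene`: list with `covariates` (list of
#'   `density`, `height`, `types` rasters), `zones` (census-filled
#'   [zone_hierarchy]), `truth` (`pop_grid` of integer persons),
#'   `truth_raw` (`grid_raster`, pre-rounding), `region_map`, `lfa_table`,
#'   `config`.
#' @export
generate_landscape <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  rows <- config$grid_shape[1]; cols <- config$grid_shape[2]
  n_cells <- rows * cols
  cs <- config$cell_size

  zones <- partition_zones(config$grid_shape, config$n_zones_per_level,
                           seed = config$seed + 1L, cell_size = cs)
  region_level <- config$region_level %||%
    { cands <- which(config$n_zones_per_level > 1L)
      if (length(cands)) cands[1] else 1L }
  region_map <- zones$levels[[region_level]]$labels
  n_regions <- zones$levels[[region_level]]$n_zones
  lfa_table <- config$lfa_table %||% default_lfa_table(n_regions)
  leaf_labels <- zones$levels[[length(zones$levels)]]$labels$values

  out <- with_seed(config$seed, {
    ## --- settlement intensity: superposed Gaussian patches + textured noise
    ri <- matrix(rep(seq_len(rows), times = cols), rows, cols)
    ci <- matrix(rep(seq_len(cols), each = rows), rows, cols)
    ns <- config$n_settlement_seeds
    sr <- stats::runif(ns, 1, rows); sc <- stats::runif(ns, 1, cols)
    amp <- stats::runif(ns, 0.5, 1)
    scale <- stats::runif(ns, 0.05, 0.14) * min(rows, cols)
    intensity <- matrix(0, rows, cols)
    nearest <- matrix(1L, rows, cols)
    best <- matrix(Inf, rows, cols)
    for (s in seq_len(ns)) {
      d2 <- (ri - sr[s])^2 + (ci - sc[s])^2
      intensity <- pmax(intensity, amp[s] * exp(-d2 / (2 * scale[s]^2)))
      upd <- d2 < best
      nearest[upd] <- s
      best[upd] <- d2[upd]
    }
    intensity <- intensity *
      exp(0.3 * disc_smooth(matrix(stats::rnorm(n_cells), rows, cols),
                            cs, 3 * cs))

    ## --- built mask and density gradient
    thr <- stats::quantile(intensity, 1 - config$urban_fraction)
    built <- intensity > thr
    dens <- matrix(0, rows, cols)
    rel <- (intensity[built] - thr) / (max(intensity) - thr)
    d <- 100 * rel^0.45 * exp(stats::rnorm(sum(built), 0, 0.15))
    dens[built] <- pmin(pmax(d, 1), 100)

    ## --- types: IC patches near IC-flagged seeds, MF cores, SF fringe,
    ##     scattered LS on low-density cells
    n_ic <- round(config$type_rules$ic_seed_frac * ns)
    ic_seeds <- if (n_ic > 0) sample(ns, n_ic) else integer(0)
    types <- matrix(TYPE_CODES[["NONE"]], rows, cols)
    types[built] <- ifelse(dens[built] >= config$type_rules$mf_min,
                           TYPE_CODES[["MF"]], TYPE_CODES[["SF"]])
    types[built & matrix(nearest %in% ic_seeds, rows, cols)] <-
      TYPE_CODES[["IC"]]
    low <- which(built & dens < 40 & types == TYPE_CODES[["SF"]])
    n_ls <- round(config$type_rules$ls_frac * sum(built))
    if (n_ls > 0 && length(low))
      types[sample(low, min(n_ls, length(low)))] <- TYPE_CODES[["LS"]]

    ## --- heights: controlled-correlation mixture of the density signal and
    ##     spatially smoothed lognormal-style noise (the smoothing emulates
    ##     the 50 m averaging of observed height products)
    height <- matrix(0, rows, cols)
    bidx <- which(built)
    zd <- dens[bidx]; zd <- (zd - mean(zd)) / stats::sd(zd)
    noise <- disc_smooth(matrix(stats::rnorm(n_cells), rows, cols), cs, 50)
    ze <- noise[bidx]; ze <- (ze - mean(ze)) / stats::sd(ze)
    r <- config$height_density_corr
    height[bidx] <- pmax(8 + 3 * (r * zd + sqrt(1 - r^2) * ze), 0.5)

    ## --- guarantee a settled hamlet in every leaf zone: census units are
    ##     drawn around settlements, so units without residents are not a
    ##     feature of real admin hierarchies
    if (config$populate_all_zones) {
      leaf_lab <- as.integer(leaf_labels)
      res25 <- as.vector((types == TYPE_CODES[["SF"]] |
                            types == TYPE_CODES[["MF"]]) & dens > 25)
      for (zz in setdiff(seq_len(max(leaf_lab)),
                         unique(leaf_lab[res25]))) {
        cells <- which(leaf_lab == zz)
        centre <- cells[sample.int(length(cells), 1)]
        cr <- (centre - 1) %% rows + 1; cc <- (centre - 1) %/% rows + 1
        d2 <- (ri[cells] - cr)^2 + (ci[cells] - cc)^2
        pick <- cells[order(d2)][seq_len(min(4L, length(cells)))]
        dens[pick] <- stats::runif(length(pick), 35, 65)
        types[pick] <- TYPE_CODES[["SF"]]
        height[pick] <- stats::runif(length(pick), 5, 9)
      }
    }

    list(dens = dens, height = height, types = types,
         noise_draw = stats::rnorm(n_cells))
  })

  density_r <- grid_raster(out$dens, cell_size = cs)
  height_r <- grid_raster(out$height, cell_size = cs)
  types_r <- grid_raster(out$types, cell_size = cs)
  covariates <- list(density = density_r, height = height_r, types = types_r)

  ## --- truth population: floor-area forward model x lognormal noise
  raw <- bu_population(covariates, region_map, lfa_table,
                       model = config$floor_model)
  noisy <- raw$values
  if (config$noise_sd > 0)
    noisy <- noisy * exp(config$noise_sd *
                           matrix(out$noise_draw, rows, cols))
  truth_raw <- raster_like(density_r, noisy)

  ## --- integerise hierarchically by largest remainder: zone totals are
  ##     rounded against the rounded global total, then cells against their
  ##     zone target, so the grand total moves < 1 person and every cell
  ##     stays within one person of the raw model
  leaf <- zones$levels[[length(zones$levels)]]
  z <- as.integer(leaf$labels$values)
  v <- as.vector(noisy)
  zone_sums <- numeric(leaf$n_zones)
  s <- rowsum(v, z)
  zone_sums[as.integer(rownames(s))] <- s[, 1]
  targets <- hamilton_round(zone_sums, round(sum(v)))
  ints <- numeric(n_cells)
  for (zz in seq_len(leaf$n_zones)) {
    i <- which(z == zz)
    ints[i] <- hamilton_round(v[i], targets[zz])
  }
  truth <- pop_grid(raster_like(density_r, ints), method = "TRUTH")
  zones <- fill_census(zones, truth)

  structure(list(covariates = covariates, zones = zones, truth = truth,
                 truth_raw = truth_raw, region_map = region_map,
                 lfa_table = lfa_table, config = config),
            class = "synth_scene")
}

#' @export
print.synth_scene <- function(x, ...) {
  d <- dim(x$truth$values)
  built <- sum(x$covariates$density$values > 0)
  cat(sprintf("<synth_scene> %d x %d cells at %g m (seed %d)\n",
              d[1], d[2], x$config$cell_size, x$config$seed))
  cat(sprintf("  built cells: %d (%.1f%%), truth population %.0f\n",
              built, 100 * built / prod(d), sum(x$truth$values)))
  tv <- x$covariates$types$values
  tab <- vapply(names(TYPE_CODES), function(nm) sum(tv == TYPE_CODES[[nm]]),
                numeric(1))
  cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  print(x$zones)
  invisible(x)
}

#' @export
plot.synth_scene <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  plot_grid_values(x$covariates$density, main = "Building density (%)")
  plot_grid_values(x$covariates$height, main = "Building height (m)")
  plot_grid_values(x$covariates$types, main = "Building type code")
  plot_grid_values(x$truth, main = "Truth population")
  invisible(x)
}

## Shared image() wrapper: row 1 is the northern edge.
plot_grid_values <- function(r, main = "", ...) {
  v <- r$values
  graphics::image(t(v[nrow(v):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = main, ...)
  invisible(r)
}
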