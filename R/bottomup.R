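#' Floor model for converting building height to habitable floor area
#'
#' Parameters of the height-to-floors conversion used by the bottom-up
#' estimator. Building height is first reduced by the roof height (default
#' 3.00 m) to discount roof space where nobody lives; buildings lower than
#' `min_height` (default 2.00 m) are excluded entirely; the remaining height
#' divided by the floor height (default 4.50 m, within the 4.00-5.55 m range
#' reported for residential buildings) gives the number of floors as a
#' decimal number, clamped below at `min_floors` (default 1.00). Living
#' floor area is floors times building footprint area times
#' `habitable_factor` (default 0.8), discounting walls and staircases.
#'
#' @param roof_height metres subtracted from building height (default 3).
#' @param floor_height metres per floor (default 4.5), must be positive.
#' @param min_height metres; buildings lower than this are excluded
#'   (default 2).
#' @param min_floors lower clamp on the decimal floor count (default 1).
#' @param habitable_factor share of floor area that is habitable, in (0, 1]
#'   (default 0.8).
#' @return an object of class `floor_model`.
#' @export
floor_model <- function(roof_height = 3, floor_height = 4.5, min_height = 2,
                        min_floors = 1, habitable_factor = 0.8) {
  if (!is.numeric(floor_height) || floor_height <= 0)
    stop("invalid parameter: `floor_height` must be positive", call. = FALSE)
  if (!is.numeric(min_floors) || min_floors < 0)
    stop("invalid parameter: `min_floors` must be >= 0", call. = FALSE)
  if (!is.numeric(habitable_factor) || habitable_factor <= 0 ||
      habitable_factor > 1)
    stop("invalid parameter: `habitable_factor` must be in (0, 1]",
         call. = FALSE)
  structure(list(roof_height = roof_height, floor_height = floor_height,
                 min_height = min_height, min_floors = min_floors,
                 habitable_factor = habitable_factor),
            class = "floor_model")
}

#' @export
print.floor_model <- function(x, ...) {
  cat(sprintf(paste0("<floor_model> roof %.2f m, floor %.2f m, exclude < ",
                     "%.2f m, min %.2f floors, habitable factor %.2f\n"),
              x$roof_height, x$floor_height, x$min_height, x$min_floors,
              x$habitable_factor))
  invisible(x)
}

#' Decimal floor count from building height
#'
#' Cells with height below `model$min_height` get 0 floors (excluded);
#' otherwise `max((height - roof_height) / floor_height, min_floors)`.
#' The exclusion is tested on raw height before the roof subtraction; the
#' clamp applies after it.
#'
#' @param height building height `grid_raster` (metres, >= 0).
#' @param model a [floor_model()].
#' @return `grid_raster` of decimal floors.
#' @export
floors_from_height <- function(height, model = floor_model()) {
  stopifnot(inherits(model, "floor_model"))
  h <- height$values
  if (any(h < 0, na.rm = TRUE))
    stop("data error: negative building height", call. = FALSE)
  f <- pmax((h - model$roof_height) / model$floor_height, model$min_floors)
  f[h < model$min_height] <- 0
  raster_like(height, f)
}

#' Living floor area per cell
#'
#' Floors times residential building footprint area times the habitable
#' factor. At 10 m cells one density percent is 1 m2 of footprint, so the
#' result is in m2 per cell.
#'
#' @param floors decimal-floor `grid_raster` from [floors_from_height()].
#' @param res_density residential building density `grid_raster` (percent).
#' @param model a [floor_model()] (supplies `habitable_factor`).
#' @return `grid_raster` of living floor area, m2 per cell.
#' @export
living_floor_area <- function(floors, res_density, model = floor_model()) {
  check_aligned(floors, res_density)
  raster_like(floors,
              floors$values * res_density$values * model$habitable_factor)
}

## Look up LFA/cap by (region, type) from a long-format table; complete
## coverage of the pairs present on residential cells is required.
lfa_lookup <- function(lfa_table, regions, type_names) {
  key <- paste(lfa_table$region, lfa_table$type, sep = "\r")
  if (anyDuplicated(key))
    stop("data error: duplicate (region, type) entry in LFA table",
         call. = FALSE)
  if (any(lfa_table$lfa_per_cap_m2 <= 0))
    stop("data error: LFA/cap values must be strictly positive",
         call. = FALSE)
  want <- paste(regions, type_names, sep = "\r")
  hit <- match(want, key)
  if (anyNA(hit)) {
    miss <- unique(want[is.na(hit)])[1]
    miss <- strsplit(miss, "\r", fixed = TRUE)[[1]]
    stop("data error: LFA table has no entry for region '", miss[1],
         "', type '", miss[2], "'", call. = FALSE)
  }
  lfa_table$lfa_per_cap_m2[hit]
}

#' Bottom-up population estimate (BU-LFA)
#'
#' Estimates persons per cell with no a-priori census total: residential
#' living floor area (from building height and residential building density)
#' divided by the living floor area per capita of the cell's region and
#' residential type,
#' \deqn{pop_{ij} = \frac{\max((bHeight_{ij} - rHeight)/fHeight,\, 1) \cdot
#'   bResDens_{ij} \cdot 0.8}{LFA/cap_{t,s}}.}
#' Only SF and MF cells contribute; IC, LS and unbuilt cells get 0. By
#' default every residential cell with positive density participates; the
#' 25 percent density threshold is a top-down masking rule and can be
#' imposed here via `min_density` if desired.
#'
#' @param covariates covariate stack with `density`, `height`, `types`.
#' @param region_map `grid_raster` of integer region labels (the LFA/cap
#'   regionalisation, e.g. state level).
#' @param lfa_table data frame with columns `region`, `type`
#'   (`"SF"`/`"MF"`), `lfa_per_cap_m2` (> 0), covering every (region, type)
#'   pair present on contributing cells.
#' @param model a [floor_model()].
#' @param min_density cells with density at or below this percent are left
#'   out (default 0: all built residential cells contribute).
#' @return a `pop_grid` (persons per cell) with provenance
#'   `method = "BU-LFA"`.
#' @export
bu_population <- function(covariates, region_map, lfa_table,
                          model = floor_model(), min_density = 0) {
  dens <- covariates$density; height <- covariates$height
  types <- covariates$types
  check_aligned_all(dens, height, types, region_map)
  check_type_codes(types)
  tv <- types$values
  res <- (tv == TYPE_CODES[["SF"]] | tv == TYPE_CODES[["MF"]]) &
    dens$values > min_density
  floors <- floors_from_height(height, model)
  pop <- matrix(0, nrow(dens$values), ncol(dens$values))
  idx <- which(res & floors$values > 0)
  if (length(idx)) {
    lfa_cell <- floors$values[idx] * dens$values[idx] * model$habitable_factor
    tnames <- ifelse(tv[idx] == TYPE_CODES[["SF"]], "SF", "MF")
    percap <- lfa_lookup(lfa_table, region_map$values[idx], tnames)
    pop[idx] <- lfa_cell / percap
  }
  pop_grid(raster_like(dens, pop), method = "BU-LFA", input_level = NA)
}

#' Total population of a grid
#'
#' @param pop a `pop_grid` or `grid_raster`.
#' @return total persons (numeric scalar).
#' @export
total_population <- function(pop) sum(pop$values)
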