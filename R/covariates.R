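#' Building density from imperviousness and infrastructure shares
#'
#' Building density is the percent of a cell covered by buildings. It is
#' obtained by subtracting the infrastructure share (roads, rails, parking
#' derived from ancillary vector data) from the impervious-surface share and
#' clamping to the physical range: `clamp(imperv - infra, 0, 100)`. At 10 m
#' cells (100 m2) one percent equals 1 m2 of building footprint.
#'
#' @param imperv `grid_raster` of impervious-surface percent in [0, 100].
#' @param infra `grid_raster` of infrastructure percent in [0, 100].
#' @return `grid_raster` of building density percent in [0, 100].
#' @export
density_from_imperviousness <- function(imperv, infra) {
  check_aligned(imperv, infra)
  for (r in list(imperv, infra)) {
    v <- r$values
    if (any(v < 0 | v > 100, na.rm = TRUE))
      stop("data error: percent raster has values outside [0, 100]",
           call. = FALSE)
  }
  raster_like(imperv, pmin(pmax(imperv$values - infra$values, 0), 100))
}

#' Binary building mask
#'
#' Marks cells that contain a building: building density strictly greater
#' than the threshold (default 25 percent).
#'
#' @param density building density `grid_raster` (percent).
#' @param threshold percent in [0, 100]; the comparison is strict (`>`).
#' @return binary `grid_raster` (0/1).
#' @export
building_mask <- function(density, threshold = 25) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 100)
    stop("invalid parameter: `threshold` must be a single percent in [0, 100]",
         call. = FALSE)
  raster_like(density, as.numeric(density$values > threshold))
}

#' Residential building mask
#'
#' Restricts a building mask to cells classified as residential (SF or MF).
#' IC and LS cells carry no de jure population and are excluded.
#'
#' @param mask binary `grid_raster` from [building_mask()].
#' @param types type-code `grid_raster` (see [TYPE_CODES]).
#' @return binary `grid_raster` (0/1).
#' @export
residential_mask <- function(mask, types) {
  check_aligned(mask, types)
  check_type_codes(types)
  res <- types$values == TYPE_CODES[["SF"]] | types$values == TYPE_CODES[["MF"]]
  raster_like(mask, as.numeric(mask$values == 1 & res))
}

#' Cell-based building volume
#'
#' Building density multiplied by building height. Units are percent-metres;
#' since one percent is 1 m2 of footprint, the value is numerically the
#' building volume in m3 per cell. Only relative magnitudes matter for
#' redistribution weights.
#'
#' @param density building density `grid_raster` (percent).
#' @param height building height `grid_raster` (metres, >= 0).
#' @return `grid_raster` of volume weights, >= 0.
#' @export
building_volume <- function(density, height) {
  check_aligned(density, height)
  if (any(height$values < 0, na.rm = TRUE))
    stop("data error: negative building height", call. = FALSE)
  raster_like(density, density$values * height$values)
}

#' Multi-family volume adjustment
#'
#' Scales the volume weight of MF (multi-family residential) cells by a
#' factor, reflecting the higher population per unit building volume of
#' multi-family housing; all other cells are unchanged. The default factor
#' 1.6 follows an empirical sensitivity analysis over candidate factors.
#'
#' @param volume volume-weight `grid_raster`.
#' @param types type-code `grid_raster`.
#' @param mf_factor positive multiplier applied to MF cells (default 1.6).
#' @return adjusted `grid_raster`.
#' @export
adjusted_volume <- function(volume, types, mf_factor = 1.6) {
  if (!is.numeric(mf_factor) || length(mf_factor) != 1L || mf_factor <= 0)
    stop("invalid parameter: `mf_factor` must be a single positive number",
         call. = FALSE)
  check_aligned(volume, types)
  check_type_codes(types)
  v <- volume$values
  mf <- types$values == TYPE_CODES[["MF"]]
  v[mf] <- v[mf] * mf_factor
  raster_like(volume, v)
}

#' Redistribution weight layers
#'
#' Builds the per-cell weight layer for one of the five dasymetric schemes,
#' a gradient of increasingly informative covariates:
#' \describe{
#'   \item{BD-BUILD}{binary: all building cells (density > threshold).}
#'   \item{BD-RESI}{binary: residential (SF/MF) building cells only.}
#'   \item{WD-DENS}{building density on residential building cells.}
#'   \item{WD-VOL}{building volume (density x height) on residential cells.}
#'   \item{WD-VOLADJ}{building volume with MF cells scaled by `mf_factor`.}
#' }
#'
#' @param method one of `"BD-BUILD"`, `"BD-RESI"`, `"WD-DENS"`, `"WD-VOL"`,
#'   `"WD-VOLADJ"` (case-insensitive).
#' @param covariates a covariate stack: list with `grid_raster` elements
#'   `density`, `height`, `types` (as produced by [generate_landscape()]).
#' @param mf_factor MF adjustment factor for WD-VOLADJ.
#' @param threshold building-mask density threshold, percent.
#' @return a `grid_raster` of nonnegative weights with attribute `method`.
#' @export
make_weights <- function(method, covariates, mf_factor = 1.6, threshold = 25) {
  method <- toupper(method)
  valid <- c("BD-BUILD", "BD-RESI", "WD-DENS", "WD-VOL", "WD-VOLADJ")
  if (!(length(method) == 1L && method %in% valid))
    stop("invalid parameter: unknown weighting method; use one of ",
         paste(valid, collapse = ", "), call. = FALSE)
  dens <- covariates$density
  mask <- building_mask(dens, threshold)
  w <- switch(method,
    "BD-BUILD" = mask,
    "BD-RESI"  = residential_mask(mask, covariates$types),
    "WD-DENS"  = {
      rm_ <- residential_mask(mask, covariates$types)
      raster_like(dens, dens$values * rm_$values)
    },
    "WD-VOL"   = {
      rm_ <- residential_mask(mask, covariates$types)
      vol <- building_volume(dens, covariates$height)
      raster_like(dens, vol$values * rm_$values)
    },
    "WD-VOLADJ" = {
      rm_ <- residential_mask(mask, covariates$types)
      vol <- adjusted_volume(building_volume(dens, covariates$height),
                             covariates$types, mf_factor)
      raster_like(dens, vol$values * rm_$values)
    })
  attr(w, "method") <- method
  w
}
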