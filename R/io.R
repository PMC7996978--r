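#' Write a raster as an Esri ASCII grid
#'
#' Plain-text, diff-able raster serialisation: a six-line header (ncols,
#' nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by rows
#' north to south. Values are written with full double precision so the
#' write/read round trip is bit-exact. NA cells are stored as the nodata
#' value.
#'
#' @param r a `grid_raster`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_asc_raster <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "grid_raster"))
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %g", nodata)), con)
  writeLines(apply(v, 1, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = " ")), con)
  invisible(path)
}

#' Read an Esri ASCII grid raster
#'
#' Counterpart of [write_asc_raster()]. If a `reference` grid is given the
#' loaded raster's grid metadata is compared against it and a mismatch is
#' an alignment error naming both grids.
#'
#' @param path input file path.
#' @param crs CRS note to attach (must be a projected metre-unit system;
#'   geographic CRS notes like `"EPSG:4326"` are rejected).
#' @param reference optional `grid_raster` defining the run's reference
#'   grid.
#' @return a `grid_raster`.
#' @export
read_asc_raster <- function(path, crs = "local-metric", reference = NULL) {
  if (!file.exists(path))
    stop("I/O error: no such file: ", path, call. = FALSE)
  if (grepl("4326|WGS ?84|longlat|geographic", crs, ignore.case = TRUE))
    stop("alignment error: geographic CRS '", crs, "' is not supported; ",
         "supply rasters in a projected metre-unit CRS", call. = FALSE)
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "[[:space:]]+")
  key <- tolower(vapply(hdr, `[`, "", 1))
  val <- as.numeric(vapply(hdr, `[`, "", 2))
  names(val) <- key
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% key))
    stop("I/O error: malformed ASCII grid header in ", path, call. = FALSE)
  nr <- as.integer(val[["nrows"]]); nc <- as.integer(val[["ncols"]])
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != nr * nc)
    stop("I/O error: expected ", nr * nc, " cells, found ", length(body),
         " in ", path, call. = FALSE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA
  r <- grid_raster(m, cell_size = val[["cellsize"]], xll = val[["xllcorner"]],
                   yll = val[["yllcorner"]], crs = crs)
  if (!is.null(reference)) check_aligned(reference, r)
  r
}

#' Read a census table
#'
#' CSV with columns `level`, `zone_id`, `population`. Counts must be
#' nonnegative integers and (level, zone_id) keys unique; violations are
#' data errors reporting the offending row.
#'
#' @param path CSV path.
#' @return named list: per level, a numeric census vector indexed by
#'   zone id.
#' @export
read_census <- function(path) {
  if (!file.exists(path))
    stop("I/O error: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("level", "zone_id", "population")
  if (!all(need %in% names(df)))
    stop("data error: census table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- which(is.na(df$population) | df$population < 0 |
                 df$population != floor(df$population))
  if (length(bad))
    stop("data error: population must be a nonnegative integer (row ",
         bad[1], ")", call. = FALSE)
  dup <- which(duplicated(df[c("level", "zone_id")]))
  if (length(dup))
    stop("data error: duplicate (level, zone_id) key (row ", dup[1], ")",
         call. = FALSE)
  out <- lapply(split(df, df$level), function(d) {
    v <- numeric(max(d$zone_id))
    v[d$zone_id] <- d$population
    v
  })
  out[unique(df$level)]
}

#' Read a living-floor-area-per-capita table
#'
#' CSV with columns `region`, `type` (`SF`/`MF`), `lfa_per_cap_m2` (> 0)
#' and optionally `year`.
#'
#' @param path CSV path.
#' @return data frame usable as `lfa_table` everywhere in the package.
#' @export
read_lfa_table <- function(path) {
  if (!file.exists(path))
    stop("I/O error: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "type", "lfa_per_cap_m2")
  if (!all(need %in% names(df)))
    stop("data error: LFA table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(!df$type %in% c("SF", "MF")))
    stop("data error: LFA `type` must be SF or MF", call. = FALSE)
  if (any(is.na(df$lfa_per_cap_m2) | df$lfa_per_cap_m2 <= 0))
    stop("data error: lfa_per_cap_m2 must be strictly positive",
         call. = FALSE)
  df
}

#' Write a synthetic scene to a directory
#'
#' Serialises every artifact as plain text: covariate rasters and zone
#' label rasters as ASCII grids, census and LFA tables as CSV with the
#' documented schemas.
#'
#' @param scene a [generate_landscape()] scene.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_asc_raster(scene$covariates$density, file.path(dir, "density.asc"))
  write_asc_raster(scene$covariates$height, file.path(dir, "height.asc"))
  write_asc_raster(scene$covariates$types, file.path(dir, "types.asc"))
  write_asc_raster(scene$truth, file.path(dir, "truth_pop.asc"))
  write_asc_raster(scene$region_map, file.path(dir, "region_map.asc"))
  for (nm in names(scene$zones$levels))
    write_asc_raster(scene$zones$levels[[nm]]$labels,
                     file.path(dir, sprintf("zones_%s.asc", nm)))
  census <- do.call(rbind, lapply(names(scene$zones$levels), function(nm) {
    lv <- scene$zones$levels[[nm]]
    data.frame(level = nm, zone_id = seq_len(lv$n_zones),
               population = lv$census)
  }))
  utils::write.csv(census, file.path(dir, "census.csv"), row.names = FALSE)
  utils::write.csv(scene$lfa_table, file.path(dir, "lfa_table.csv"),
                   row.names = FALSE)
  invisible(dir)
}
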