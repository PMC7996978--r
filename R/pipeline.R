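#' Run the full estimation pipeline
#'
#' Orchestrates scene simulation (or loading), top-down redistribution with
#' one or more weighting methods, the bottom-up estimate, and validation,
#' writing every product as plain text plus a machine-readable run
#' manifest. Given identical configuration and seed the outputs are
#' identical.
#'
#' @param config a list (or path to a JSON file encoding one) with
#'   elements: `out_dir`; `seed`; `methods` (subset of BD-BUILD, BD-RESI,
#'   WD-DENS, WD-VOL, WD-VOLADJ); optional `scene` (arguments to
#'   [scene_config()]) to simulate, or `scene_dir` to load a directory
#'   written by [write_scene()]; optional `mf_factor` (default 1.6),
#'   `input_level` (default 1), `validation_level` (default finest),
#'   `fallback` (default "uniform"), `bottomup` (logical, default TRUE),
#'   `best_product` (logical, default TRUE).
#' @param quiet suppress stage messages.
#' @return invisibly, a list with the scene, the population grids and the
#'   validation reports; artifacts are written under `config$out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$out_dir))
    stop("invalid configuration: `out_dir` is required", call. = FALSE)
  methods <- toupper(config$methods %||%
                       c("BD-BUILD", "BD-RESI", "WD-DENS", "WD-VOL",
                         "WD-VOLADJ"))
  valid <- c("BD-BUILD", "BD-RESI", "WD-DENS", "WD-VOL", "WD-VOLADJ")
  if (!all(methods %in% valid))
    stop("invalid parameter: unknown method(s): ",
         paste(setdiff(methods, valid), collapse = ", "), call. = FALSE)
  seed <- config$seed %||% 1L
  say <- function(...) if (!quiet) message("[gridpop] ", sprintf(...))

  say("stage simulate: building scene (seed %d)", seed)
  scene <- tryCatch({
    if (!is.null(config$scene_dir)) read_scene(config$scene_dir)
    else {
      args <- config$scene %||% list()
      args$seed <- seed
      generate_landscape(do.call(scene_config, args))
    }
  }, error = function(e) stop("stage simulate: ", conditionMessage(e),
                              call. = FALSE))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_scene(scene, file.path(config$out_dir, "scene"))

  input_level <- config$input_level %||% 1
  validation_level <- config$validation_level %||%
    length(scene$zones$levels)
  mf_factor <- config$mf_factor %||% 1.6
  fallback <- config$fallback %||% "uniform"

  grids <- list(); reports <- list()
  for (m in methods) {
    say("stage topdown: %s", m)
    pop <- tryCatch({
      w <- make_weights(m, scene$covariates, mf_factor = mf_factor)
      redistribute(scene$zones, w, fallback = fallback,
                   which_level = input_level)
    }, error = function(e) stop("stage topdown(", m, "): ",
                                conditionMessage(e), call. = FALSE))
    grids[[m]] <- pop
    reports[[m]] <- validate_grid(pop, scene$zones, validation_level)
    write_asc_raster(pop, file.path(config$out_dir,
                                    sprintf("pop_%s.asc", tolower(m))))
  }
  if (isTRUE(config$best_product %||% TRUE)) {
    say("stage topdown: best product (finest level, WD-VOLADJ)")
    bp <- best_product(scene$zones, scene$covariates, mf_factor = mf_factor)
    grids[["BEST"]] <- bp
    write_asc_raster(bp, file.path(config$out_dir, "pop_best_product.asc"))
  }
  if (isTRUE(config$bottomup %||% TRUE)) {
    say("stage bottomup: BU-LFA")
    bu <- tryCatch(
      bu_population(scene$covariates, scene$region_map, scene$lfa_table,
                    model = scene$config$floor_model %||% floor_model()),
      error = function(e) stop("stage bottomup: ", conditionMessage(e),
                               call. = FALSE))
    grids[["BU-LFA"]] <- bu
    reports[["BU-LFA"]] <- validate_grid(bu, scene$zones, validation_level)
    write_asc_raster(bu, file.path(config$out_dir, "pop_bu_lfa.asc"))
  }

  say("stage validate: writing reports")
  rep_json <- lapply(reports, function(r)
    list(level = r$level, method = r$method, metrics = r$metrics,
         asr = r$asr, histogram = r$histogram, n_excluded = r$n_excluded))
  jsonlite::write_json(rep_json,
                       file.path(config$out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (m in names(reports))
    utils::write.csv(reports[[m]]$table,
                     file.path(config$out_dir,
                               sprintf("zones_%s.csv", tolower(m))),
                     row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gridpop")),
    r_version = as.character(getRversion()),
    seed = seed, methods = methods, mf_factor = mf_factor,
    input_level = input_level, validation_level = validation_level,
    config = config[setdiff(names(config), "scene")],
    config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(scene = scene, grids = grids, reports = reports))
}

## Stable content hash of a configuration: md5 of its canonical JSON.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Read a scene directory written by [write_scene()]
#'
#' @param dir directory path.
#' @return a `synth_scene`-shaped list (without the generating config).
#' @export
read_scene <- function(dir) {
  density <- read_asc_raster(file.path(dir, "density.asc"))
  height <- read_asc_raster(file.path(dir, "height.asc"),
                            reference = density)
  types <- read_asc_raster(file.path(dir, "types.asc"), reference = density)
  truth <- read_asc_raster(file.path(dir, "truth_pop.asc"),
                           reference = density)
  region_map <- read_asc_raster(file.path(dir, "region_map.asc"),
                                reference = density)
  census <- read_census(file.path(dir, "census.csv"))
  zone_files <- sort(list.files(dir, pattern = "^zones_.*\\.asc$"))
  level_names <- sub("^zones_(.*)\\.asc$", "\\1", zone_files)
  ## keep the census table's level order (coarse to fine)
  level_names <- intersect(names(census), level_names)
  levels <- lapply(level_names, function(nm) {
    labels <- read_asc_raster(file.path(dir, sprintf("zones_%s.asc", nm)),
                              reference = density)
    n <- max(labels$values)
    area <- as.numeric(table(factor(labels$values, levels = seq_len(n)))) *
      (density$cell_size / 1000)^2
    list(labels = labels, n_zones = n, census = census[[nm]],
         area_km2 = area)
  })
  names(levels) <- level_names
  zones <- structure(
    list(levels = levels, cell_size = density$cell_size,
         total_area_km2 = prod(dim(density$values)) *
           (density$cell_size / 1000)^2),
    class = "zone_hierarchy")
  structure(list(
    covariates = list(density = density, height = height, types = types),
    zones = zones,
    truth = pop_grid(truth, method = "TRUTH"),
    truth_raw = NULL,
    region_map = region_map,
    lfa_table = read_lfa_table(file.path(dir, "lfa_table.csv")),
    config = NULL), class = "synth_scene")
}
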