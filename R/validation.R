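#' Aggregate a population grid to zones
#'
#' Exact per-zone cell sums of a population grid at one hierarchy level.
#'
#' @param pop `pop_grid` or `grid_raster`.
#' @param level one level of a [zone_hierarchy] (or a hierarchy plus
#'   `which_level`).
#' @param which_level level name/index when `level` is a full hierarchy.
#' @return numeric vector of persons, indexed by zone id.
#' @export
aggregate_to_zones <- function(pop, level, which_level = NULL) {
  if (inherits(level, "zone_hierarchy"))
    level <- get_level(level, which_level)
  check_aligned(pop, level$labels)
  z <- as.integer(level$labels$values)
  s <- rowsum(as.vector(pop$values), z)
  out <- numeric(level$n_zones)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Relative estimation error (signed, percent)
#'
#' `100 * (est - ref) / ref` per validation unit. Units with zero reference
#' population are undefined and must be excluded by the caller (see
#' [validate_grid()], which tallies them separately).
#'
#' @param est,ref estimated and reference persons (vectors).
#' @return signed percent errors.
#' @export
ree <- function(est, ref) {
  if (any(ref <= 0))
    stop("invalid parameter: REE requires reference > 0; exclude ",
         "zero-reference zones first", call. = FALSE)
  100 * (est - ref) / ref
}

#' Aggregate quality metrics over validation units
#'
#' MAPE (mean of |REE| across units, unweighted), MAE, RMSE, and the slope
#' and R-squared of an ordinary least-squares fit of estimate on reference
#' with free intercept (set `through_origin = TRUE` for a no-intercept
#' fit). Zones with zero reference are excluded from every metric.
#'
#' @param est,ref estimated and reference persons per unit.
#' @param through_origin fit the est~ref regression without intercept.
#' @return named list: `mape`, `mae`, `rmse`, `r_squared`, `slope`,
#'   `n_units`, `n_excluded`.
#' @export
summary_metrics <- function(est, ref, through_origin = FALSE) {
  stopifnot(length(est) == length(ref))
  keep <- ref > 0
  if (!any(keep))
    stop("undefined metrics: every unit has zero reference population",
         call. = FALSE)
  n_excluded <- sum(!keep)
  est <- est[keep]; ref <- ref[keep]
  if (length(ref) < 2L)
    stop("undefined metrics: need at least 2 units with positive reference",
         call. = FALSE)
  err <- est - ref
  fit <- if (through_origin) stats::lm(est ~ ref + 0)
         else stats::lm(est ~ ref)
  list(mape = mean(abs(ree(est, ref))),
       mae = mean(abs(err)),
       rmse = sqrt(mean(err^2)),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       slope = unname(stats::coef(fit)[["ref"]]),
       n_units = length(ref), n_excluded = n_excluded)
}

## Signed REE bin edges; REE of exactly 0 goes to the (0, 10] bin, and each
## edge is closed on the side away from zero.
REE_BREAKS <- c(-Inf, -100, -50, -25, -10, 0, 10, 25, 50, 100, Inf)
REE_BIN_LABELS <- c("<=-100", "(-100,-50]", "(-50,-25]", "(-25,-10]",
                    "(-10,0)", "[0,10]", "(10,25]", "(25,50]", "(50,100]",
                    ">100")

#' Histogram of REE over validation units
#'
#' Ten signed bins of over- and underestimation (0-10, 10-25, 25-50,
#' 50-100, >100 percent on each side). For every bin both the number of
#' units and their total reference population are tallied; both tallies are
#' conserved (bins partition the included units).
#'
#' @param ree_values signed REE percent per unit.
#' @param ref reference persons per unit (same order).
#' @return data frame: `bin`, `n_zones`, `ref_population`.
#' @export
ree_histogram <- function(ree_values, ref) {
  stopifnot(length(ree_values) == length(ref))
  x <- ree_values
  x[x == 0] <- .Machine$double.eps  # zero counts as (non-negative) 0-10 bin
  idx <- cut(x, breaks = REE_BREAKS, right = TRUE, labels = FALSE)
  data.frame(
    bin = factor(REE_BIN_LABELS, levels = REE_BIN_LABELS),
    n_zones = vapply(seq_along(REE_BIN_LABELS),
                     function(b) sum(idx == b), numeric(1)),
    ref_population = vapply(seq_along(REE_BIN_LABELS),
                            function(b) sum(ref[idx == b]), numeric(1))
  )
}

#' Average spatial resolution (ASR)
#'
#' The square root of total area divided by the number of administrative
#' units, in km: the edge length of the mean unit if units were square.
#'
#' @param total_area_km2 total area in km2 (> 0).
#' @param n_units number of units (>= 1).
#' @return ASR in km.
#' @export
asr <- function(total_area_km2, n_units) {
  if (length(n_units) != 1L || is.na(n_units) || n_units < 1)
    stop("invalid parameter: `n_units` must be >= 1", call. = FALSE)
  if (total_area_km2 <= 0)
    stop("invalid parameter: `total_area_km2` must be positive",
         call. = FALSE)
  sqrt(total_area_km2 / n_units)
}

#' ASR ratio between census input and validation levels
#'
#' `ASR(input) / ASR(validation)` over the same total area, i.e.
#' `sqrt(n_validation / n_input)`. Large ratios mean a large offset in
#' spatial scale between the level providing census input and the level
#' used for validation; for a single input unit the ratio is exactly the
#' square root of the number of validation units.
#'
#' @param n_input,n_validation unit counts of the two levels.
#' @param total_area_km2 total area (cancels; used for validity checks).
#' @return the dimensionless ASR ratio.
#' @export
asr_ratio <- function(n_input, n_validation, total_area_km2 = 1) {
  asr(total_area_km2, n_input) / asr(total_area_km2, n_validation)
}

#' Validate a population grid against a census level
#'
#' Aggregates the grid to the validation level, computes per-zone signed
#' REE, the aggregate metrics of [summary_metrics()], the REE histogram,
#' and the ASR bookkeeping for the grid's census input level versus the
#' validation level.
#'
#' @param pop a `pop_grid`.
#' @param zones a census-filled [zone_hierarchy].
#' @param which_level validation level name or index.
#' @param through_origin passed to [summary_metrics()].
#' @return object of class `pop_validation`: `level`, `method`, `table`
#'   (zone_id, reference, estimate, ree; excluded zones have NA ree),
#'   `metrics`, `histogram`, `asr`, `n_excluded`.
#' @export
validate_grid <- function(pop, zones, which_level, through_origin = FALSE) {
  lv <- get_level(zones, which_level)
  level_name <- if (is.character(which_level)) which_level
                else names(zones$levels)[which_level]
  est <- aggregate_to_zones(pop, lv)
  ref <- lv$census
  keep <- ref > 0
  tab <- data.frame(zone_id = seq_along(ref), reference = ref,
                    estimate = est, ree = NA_real_)
  tab$ree[keep] <- ree(est[keep], ref[keep])
  metrics <- summary_metrics(est, ref, through_origin = through_origin)
  hist <- ree_histogram(tab$ree[keep], ref[keep])

  asr_val <- asr(zones$total_area_km2, lv$n_zones)
  input_n <- if (!is.na(pop$input_level) &&
                 pop$input_level %in% names(zones$levels))
    zones$levels[[pop$input_level]]$n_zones else NA_integer_
  asr_info <- list(
    validation_km = asr_val,
    input_km = if (!is.na(input_n)) asr(zones$total_area_km2, input_n)
               else NA_real_,
    ratio = if (!is.na(input_n)) asr_ratio(input_n, lv$n_zones) else NA_real_)

  structure(list(level = level_name, method = pop$method,
                 input_level = pop$input_level, table = tab,
                 metrics = metrics, histogram = hist, asr = asr_info,
                 n_excluded = metrics$n_excluded),
            class = "pop_validation")
}

#' @export
print.pop_validation <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<pop_validation> %s at level %s (input level %s)\n",
              x$method, x$level, x$input_level))
  cat(sprintf("  units: %d validated, %d excluded (zero reference)\n",
              m$n_units, m$n_excluded))
  cat(sprintf("  MAPE %.2f%%  MAE %.2f  RMSE %.2f  R2 %.4f  slope %.4f\n",
              m$mape, m$mae, m$rmse, m$r_squared, m$slope))
  if (!is.na(x$asr$ratio))
    cat(sprintf("  ASR: input %.3f km, validation %.3f km, ratio %.2f\n",
                x$asr$input_km, x$asr$validation_km, x$asr$ratio))
  invisible(x)
}

#' @export
summary.pop_validation <- function(object, ...) {
  print(object)
  cat("REE histogram (units / reference population):\n")
  print(object$histogram, row.names = FALSE)
  invisible(object)
}

#' @export
plot.pop_validation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tab <- x$table[!is.na(x$table$ree), ]
  graphics::plot(tab$reference, tab$estimate, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "Reference population", ylab = "Estimate",
                 main = sprintf("%s at %s", x$method, x$level))
  graphics::abline(0, 1, lty = 2)
  graphics::barplot(x$histogram$n_zones,
                    names.arg = x$histogram$bin, las = 2,
                    cex.names = 0.6, main = "REE bins (units)",
                    col = "grey70")
  invisible(x)
}

#' Sensitivity of top-down quality to the MF volume adjustment factor
#'
#' Runs WD-VOLADJ redistribution for each candidate factor and reports the
#' validation metrics; the factor minimising MAPE is flagged. With a factor
#' of 1 the scheme coincides with WD-VOL.
#'
#' @param scene a [generate_landscape()] scene.
#' @param factors positive candidate MF factors.
#' @param input_level census input level (default 1, the coarsest).
#' @param validation_level level for MAPE (default the finest).
#' @return data frame of `mf_factor`, `mape`, `mae`, `rmse`, `r_squared`,
#'   `slope`, with attribute `best_factor`.
#' @export
mf_factor_sweep <- function(scene, factors = seq(1, 2, by = 0.2),
                            input_level = 1,
                            validation_level = length(scene$zones$levels)) {
  if (length(factors) == 0L || any(factors <= 0))
    stop("invalid parameter: `factors` must be a nonempty positive vector",
         call. = FALSE)
  rows <- lapply(factors, function(f) {
    w <- make_weights("WD-VOLADJ", scene$covariates, mf_factor = f)
    pop <- redistribute(scene$zones, w, which_level = input_level)
    m <- validate_grid(pop, scene$zones, validation_level)$metrics
    data.frame(mf_factor = f, mape = m$mape, mae = m$mae, rmse = m$rmse,
               r_squared = m$r_squared, slope = m$slope)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_factor") <- out$mf_factor[which.min(out$mape)]
  out
}

#' Temporal sensitivity of the bottom-up estimate
#'
#' Re-estimates the bottom-up population with LFA/cap tables from other
#' years and compares each year's per-zone estimates to the base year:
#' because the estimator is linear in 1/LFA/cap, uniformly smaller LFA/cap
#' uniformly raises estimates.
#'
#' @param scene a scene.
#' @param lfa_series named list, year -> LFA table.
#' @param base_year name of the base-year entry.
#' @param which_level zone level for the per-zone ratio distribution.
#' @param model a [floor_model()].
#' @return data frame per year: `year`, `total`, and summary columns of
#'   the per-zone ratio distribution (`ratio_min`, `ratio_median`,
#'   `ratio_max`); attribute `ratios` holds the full matrix.
#' @export
sensitivity_temporal <- function(scene, lfa_series, base_year,
                                 which_level = length(scene$zones$levels),
                                 model = floor_model()) {
  if (!base_year %in% names(lfa_series))
    stop("data error: base year '", base_year, "' missing from the series",
         call. = FALSE)
  lv <- get_level(scene$zones, which_level)
  est_one <- function(tab)
    aggregate_to_zones(bu_population(scene$covariates, scene$region_map,
                                     tab, model = model), lv)
  base <- est_one(lfa_series[[base_year]])
  keep <- base > 0
  years <- names(lfa_series)
  ratios <- sapply(years, function(y) est_one(lfa_series[[y]])[keep] /
                     base[keep])
  totals <- vapply(years, function(y)
    total_population(bu_population(scene$covariates, scene$region_map,
                                   lfa_series[[y]], model = model)),
    numeric(1))
  out <- data.frame(year = years, total = totals,
                    ratio_min = apply(ratios, 2, min),
                    ratio_median = apply(ratios, 2, stats::median),
                    ratio_max = apply(ratios, 2, max),
                    row.names = NULL)
  attr(out, "ratios") <- ratios
  out
}

#' Spatial sensitivity: one region's LFA/cap applied everywhere
#'
#' Replaces the regionalised LFA/cap with a single donor region's
#' type-specific values across the whole scene and compares per-zone
#' estimates to the regionalised model.
#'
#' @param scene a scene.
#' @param donor_region region id whose LFA/cap is applied everywhere.
#' @param which_level zone level for the ratio distribution.
#' @param model a [floor_model()].
#' @return list: `total`, `total_regionalized`, `ratios` (per-zone, over
#'   zones with positive regionalised estimate).
#' @export
sensitivity_spatial <- function(scene, donor_region,
                                which_level = length(scene$zones$levels),
                                model = floor_model()) {
  tab <- scene$lfa_table
  donor <- tab[tab$region == donor_region, ]
  if (nrow(donor) == 0L)
    stop("data error: donor region '", donor_region,
         "' missing from the LFA table", call. = FALSE)
  regions <- unique(tab$region)
  donor_tab <- do.call(rbind, lapply(regions, function(r) {
    d <- donor; d$region <- r; d
  }))
  lv <- get_level(scene$zones, which_level)
  reg_pop <- bu_population(scene$covariates, scene$region_map, tab,
                           model = model)
  don_pop <- bu_population(scene$covariates, scene$region_map, donor_tab,
                           model = model)
  reg_z <- aggregate_to_zones(reg_pop, lv)
  don_z <- aggregate_to_zones(don_pop, lv)
  keep <- reg_z > 0
  list(total = total_population(don_pop),
       total_regionalized = total_population(reg_pop),
       ratios = don_z[keep] / reg_z[keep])
}
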