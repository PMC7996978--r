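test_that("zonal aggregation is exact and matches the dictionary oracle", {
  lab <- matrix(1, 5, 10)
  lv <- manual_level(lab, census = 0)
  ones <- grid_raster(matrix(1, 5, 10))
  expect_equal(aggregate_to_zones(ones, lv), 50)
  set.seed(7)
  for (k in 1:20) {
    n <- 8
    nz <- sample(2:6, 1)
    lab <- matrix(sample(nz, n * n, replace = TRUE), n, n)
    pop <- grid_raster(matrix(runif(n * n, 0, 10), n, n))
    lv <- manual_level(lab, census = numeric(nz))
    expect_equal(aggregate_to_zones(pop, lv),
                 oracle_aggregate(pop$values, lab, nz), tolerance = 1e-12)
  }
})

test_that("REE is the signed percent deviation from reference", {
  expect_equal(ree(110, 100), 10)
  expect_equal(ree(150, 200), -25)
  expect_equal(ree(100, 100), 0)
  expect_equal(ree(c(110, 150), c(100, 200)), c(10, -25))
  expect_error(ree(5, 0), "reference > 0")
})

test_that("summary metrics match closed-form least squares and hand values", {
  m <- summary_metrics(c(110, 150), c(100, 200))
  expect_equal(m$mape, 17.5)
  expect_equal(m$mae, 30)
  expect_equal(m$rmse, sqrt(1300))
  # perfect estimates
  p <- summary_metrics(c(5, 10, 20), c(5, 10, 20))
  expect_equal(p$mape, 0)
  expect_equal(p$slope, 1)
  expect_equal(p$r_squared, 1)
  # random 20-zone instance vs an independent closed-form computation
  set.seed(11)
  ref <- runif(20, 50, 500)
  est <- ref * runif(20, 0.7, 1.3)
  m2 <- summary_metrics(est, ref)
  sxx <- sum((ref - mean(ref))^2)
  sxy <- sum((ref - mean(ref)) * (est - mean(est)))
  slope_cf <- sxy / sxx
  r2_cf <- sxy^2 / (sxx * sum((est - mean(est))^2))
  expect_equal(m2$slope, slope_cf, tolerance = 1e-10)
  expect_equal(m2$r_squared, r2_cf, tolerance = 1e-10)
  expect_equal(m2$mape, mean(abs(100 * (est - ref) / ref)))
  # zero-reference zones are excluded and tallied
  m3 <- summary_metrics(c(1, 2, 9), c(0, 2, 10))
  expect_equal(m3$n_excluded, 1)
  expect_equal(m3$n_units, 2)
  expect_error(summary_metrics(c(1, 2), c(0, 0)), "undefined metrics")
})

test_that("REE histogram bins, conserves and places zero on the positive side", {
  ree_v <- c(-60, -30, -15, -5, 5, 30, 120)
  ref <- c(10, 20, 30, 40, 50, 60, 70)
  h <- ree_histogram(ree_v, ref)
  expect_equal(sum(h$n_zones), length(ree_v))
  expect_equal(sum(h$ref_population), sum(ref))
  got <- h$n_zones
  names(got) <- as.character(h$bin)
  expect_equal(unname(got[c("(-100,-50]", "(-50,-25]", "(-25,-10]",
                            "(-10,0)", "[0,10]", "(25,50]", ">100")]),
               rep(1, 7))
  expect_equal(sum(got), 7)
  # REE exactly 0 lands in the nonnegative 0-10 bin
  h0 <- ree_histogram(c(0, 0), c(1, 2))
  expect_equal(h0$n_zones[h0$bin == "[0,10]"], 2)
  # closed-away-from-zero edges: -10 is in (-25,-10], +10 in [0,10]
  he <- ree_histogram(c(-10, 10), c(1, 1))
  expect_equal(he$n_zones[he$bin == "(-25,-10]"], 1)
  expect_equal(he$n_zones[he$bin == "[0,10]"], 1)
})

test_that("ASR and ASR ratio follow the square-root definitions", {
  expect_equal(asr(100, 4), 5)
  expect_equal(asr(64, 1), 8)
  expect_equal(asr(357000, 11267), 5.63, tolerance = 0.01)
  expect_error(asr(100, 0), "invalid parameter")
  expect_error(asr(0, 4), "invalid parameter")
  expect_equal(asr_ratio(1, 4), 2)
  expect_equal(asr_ratio(5, 5), 1)
  expect_equal(asr_ratio(1, 401), sqrt(401))
})

test_that("validate_grid assembles a consistent report", {
  sc <- small_scene(seed = 4)
  pop <- redistribute(sc$zones, make_weights("WD-VOL", sc$covariates),
                      which_level = 1)
  v <- validate_grid(pop, sc$zones, length(sc$zones$levels))
  inc <- !is.na(v$table$ree)
  # MAPE is the mean absolute REE over included zones
  expect_equal(v$metrics$mape, mean(abs(v$table$ree[inc])))
  # histogram tallies conserve zones and reference population
  expect_equal(sum(v$histogram$n_zones), sum(inc))
  expect_equal(sum(v$histogram$ref_population),
               sum(v$table$reference[inc]))
  # ASR ratio bookkeeping: input level 1 has a single zone here
  expect_equal(v$asr$ratio,
               sqrt(sc$zones$levels[[length(sc$zones$levels)]]$n_zones))
  expect_output(print(v), "MAPE")
})

test_that("MF factor sweep reports metrics per factor and flags the argmin", {
  sc <- small_scene(seed = 5)
  sw <- mf_factor_sweep(sc, factors = c(1.0, 1.6))
  expect_equal(nrow(sw), 2)
  expect_true(all(is.finite(sw$mape)))
  # factor 1 coincides with WD-VOL
  pop <- redistribute(sc$zones, make_weights("WD-VOL", sc$covariates),
                      which_level = 1)
  m <- validate_grid(pop, sc$zones, length(sc$zones$levels))$metrics
  expect_equal(sw$mape[sw$mf_factor == 1], m$mape)
  expect_error(mf_factor_sweep(sc, factors = numeric(0)),
               "invalid parameter")
})

test_that("temporal sensitivity is governed by the estimator's linearity", {
  sc <- small_scene(seed = 6)
  series <- list("2018" = sc$lfa_table,
                 "2010" = transform(sc$lfa_table,
                                    lfa_per_cap_m2 = lfa_per_cap_m2 * 0.9))
  out <- sensitivity_temporal(sc, series, base_year = "2018")
  base <- out[out$year == "2018", ]
  expect_equal(base$ratio_min, 1)
  expect_equal(base$ratio_max, 1)
  # uniformly 10% smaller LFA/cap inflates every zone by exactly 1/0.9
  old <- out[out$year == "2010", ]
  expect_equal(old$ratio_min, 1 / 0.9, tolerance = 1e-10)
  expect_equal(old$ratio_max, 1 / 0.9, tolerance = 1e-10)
  expect_error(sensitivity_temporal(sc, series, base_year = "1999"),
               "missing")
})

test_that("spatial sensitivity responds to donor atypicality", {
  sc <- small_scene(seed = 7)
  # donor identical to the regionalised table in a 1-region scene
  sc1 <- generate_landscape(scene_config(grid_shape = c(32, 32),
                                         n_zones_per_level = c(1, 2),
                                         region_level = 1, seed = 3))
  out1 <- sensitivity_spatial(sc1, donor_region = 1)
  expect_equal(out1$ratios, rep(1, length(out1$ratios)))
  # donor with half of everyone's LFA/cap exactly doubles the total:
  # uniform table at 40 (SF) / 30 (MF), donor region at half those values
  regions <- sort(unique(sc$lfa_table$region))
  uniform <- rbind(
    data.frame(region = regions, type = "SF", lfa_per_cap_m2 = 40),
    data.frame(region = regions, type = "MF", lfa_per_cap_m2 = 30))
  halved <- uniform
  halved$lfa_per_cap_m2[halved$region == regions[1]] <-
    halved$lfa_per_cap_m2[halved$region == regions[1]] / 2
  sc_h <- sc
  sc_h$lfa_table <- halved
  out2 <- sensitivity_spatial(sc_h, donor_region = regions[1])
  full <- total_population(
    bu_population(sc$covariates, sc$region_map, uniform))
  expect_equal(out2$total, 2 * full, tolerance = 1e-9)
  # ratio spread widens with donor atypicality: compare an identical,
  # a mildly and a strongly deviating donor
  spread <- sapply(c(1, 1.3, 2), function(k) {
    tab <- uniform
    tab$lfa_per_cap_m2[tab$region == regions[1]] <-
      tab$lfa_per_cap_m2[tab$region == regions[1]] / k
    sc_k <- sc
    sc_k$lfa_table <- tab
    stats::sd(sensitivity_spatial(sc_k, donor_region = regions[1])$ratios)
  })
  expect_true(all(diff(spread) >= 0))
  expect_error(sensitivity_spatial(sc, donor_region = 999), "missing")
})
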