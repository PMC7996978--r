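test_that("redistribution matches hand-computed shares", {
  lab <- matrix(1, 2, 2)
  lv <- manual_level(lab, census = 100)
  w <- tiny_raster(rep(1, 4))
  pop <- redistribute(lv, w)
  expect_equal(as.vector(pop$values), rep(25, 4))

  # a single weighted cell takes the whole count; scale invariance
  w2 <- tiny_raster(c(2, 0, 0, 0))
  lv7 <- manual_level(lab, census = 7)
  expect_equal(as.vector(redistribute(lv7, w2)$values), c(7, 0, 0, 0))
  w200 <- tiny_raster(c(200, 0, 0, 0))
  expect_equal(redistribute(lv7, w200)$values, redistribute(lv7, w2)$values)

  # two zones, forced by the weighting formula
  lab2 <- matrix(c(1, 1, 1, 2, 2, 2), 2, 3)
  lv2 <- manual_level(lab2, census = c(60, 40))
  w3 <- grid_raster(matrix(c(1, 2, 3, 5, 0, 5), 2, 3))
  pop2 <- redistribute(lv2, w3)
  expect_equal(as.vector(pop2$values), c(10, 20, 30, 20, 0, 20))
})

test_that("redistribution equals the per-cell loop oracle on random instances", {
  set.seed(101)
  worst <- 0
  for (k in 1:100) {
    n <- sample(8:16, 1)
    nz <- sample(2:5, 1)
    lab <- matrix(sample(nz, n * n, replace = TRUE), n, n)
    for (z in 1:nz) if (!any(lab == z)) lab[sample(n * n, 1)] <- z
    wm <- matrix(rexp(n * n) * rbinom(n * n, 1, 0.8), n, n)
    census <- rpois(nz, 500)
    # guard the all-zero-weight case (exercised separately below)
    for (z in 1:nz) if (sum(wm[lab == z]) == 0) wm[which(lab == z)[1]] <- 1
    lv <- manual_level(lab, census)
    got <- redistribute(lv, grid_raster(wm))$values
    want <- oracle_redistribute(lab, wm, census)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lte(worst, 1e-12)
})

test_that("redistribution conserves census mass per zone and globally", {
  for (s in 1:5) {
    sc <- small_scene(seed = s)
    for (m in c("BD-BUILD", "BD-RESI", "WD-DENS", "WD-VOL", "WD-VOLADJ")) {
      w <- make_weights(m, sc$covariates)
      for (l in seq_along(sc$zones$levels)) {
        pop <- suppressWarnings(
          redistribute(sc$zones, w, which_level = l))
        lv <- sc$zones$levels[[l]]
        agg <- aggregate_to_zones(pop, lv)
        pos <- lv$census > 0
        expect_lte(max(abs(agg[pos] - lv$census[pos]) / lv$census[pos]),
                   1e-9)
        expect_equal(sum(pop$values), sum(lv$census), tolerance = 1e-9)
        expect_true(all(agg[!pos] == 0))  # empty census -> empty estimate
      }
    }
  }
})

test_that("binary weights reproduce the binary dasymetric formula exactly", {
  sc <- small_scene(seed = 1)
  w <- make_weights("BD-BUILD", sc$covariates)
  pop <- redistribute(sc$zones, w, which_level = 1)
  inh <- w$values
  manual <- inh * sum(sc$zones$levels[[1]]$census) / sum(inh)
  expect_equal(pop$values, manual, tolerance = 1e-12)
  # every admissible cell holds an equal share
  expect_length(unique(round(pop$values[inh == 1], 12)), 1)
})

test_that("zero-weight zones with census follow the fallback policy", {
  lab <- matrix(c(1, 1, 2, 2), 2, 2)
  lv <- manual_level(lab, census = c(10, 8))
  w <- tiny_raster(c(1, 3, 0, 0))  # zone 2 has census but no weight
  expect_warning(pop <- redistribute(lv, w, fallback = "uniform"),
                 "fallback")
  expect_equal(as.vector(pop$values), c(2.5, 7.5, 4, 4))
  expect_error(redistribute(lv, w, fallback = "strict"), "all-zero weights")
  # cells with zero weight in a healthy zone receive exactly zero
  w3 <- tiny_raster(c(1, 0, 2, 2))
  expect_equal(redistribute(lv, w3)$values[2, 1], 0)
})

test_that("best product is leaf-level WD-VOLADJ and conserves leaf census", {
  sc <- small_scene(seed = 2)
  bp <- suppressWarnings(best_product(sc$zones, sc$covariates))
  leaf <- sc$zones$levels[[length(sc$zones$levels)]]
  agg <- aggregate_to_zones(bp, leaf)
  pos <- leaf$census > 0
  expect_lte(max(abs(agg[pos] - leaf$census[pos]) / leaf$census[pos]), 1e-9)
  # with a single leaf zone it coincides with national WD-VOLADJ
  sc1 <- generate_landscape(scene_config(grid_shape = c(32, 32),
                                         n_zones_per_level = 1, seed = 5))
  w <- make_weights("WD-VOLADJ", sc1$covariates)
  expect_equal(best_product(sc1$zones, sc1$covariates)$values,
               redistribute(sc1$zones, w, which_level = 1)$values)
})

test_that("finer census input never does worse at its own or coarser levels", {
  # leaf-level input reproduces leaf census, so leaf MAPE is ~0 while
  # national input leaves genuine error; check across seeds
  for (s in 1:5) {
    sc <- small_scene(seed = s)
    w <- make_weights("WD-VOLADJ", sc$covariates)
    nlev <- length(sc$zones$levels)
    coarse <- redistribute(sc$zones, w, which_level = 1)
    fine <- suppressWarnings(redistribute(sc$zones, w, which_level = nlev))
    m_coarse <- validate_grid(coarse, sc$zones, nlev)$metrics$mape
    m_fine <- validate_grid(fine, sc$zones, nlev)$metrics$mape
    expect_lte(m_fine, m_coarse)
  }
})

test_that("integer export conserves rounded totals and moves cells < 1", {
  sc <- small_scene(seed = 3)
  w <- make_weights("WD-VOL", sc$covariates)
  pop <- redistribute(sc$zones, w, which_level = 1)
  ints <- integerize_population(pop, sc$zones)
  expect_true(all(ints$values == floor(ints$values)))
  expect_lt(max(abs(ints$values - pop$values)), 1)
  leaf <- sc$zones$levels[[length(sc$zones$levels)]]
  expect_equal(aggregate_to_zones(ints, leaf),
               round(aggregate_to_zones(pop, leaf)))
})
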