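test_that("zone partitions are exact and nested", {
  # single zone covers everything
  zh <- partition_zones(c(10, 10), 1)
  expect_equal(unique(as.vector(zh$levels[[1]]$labels$values)), 1)
  # two children partition the grid
  zh <- partition_zones(c(10, 10), c(1, 2))
  lab <- zh$levels[[2]]$labels$values
  expect_setequal(unique(as.vector(lab)), 1:2)
  expect_equal(sum(lab == 1) + sum(lab == 2), 100)
  # 1/4/16 on 100x100: every leaf zone inside exactly one parent
  zh <- partition_zones(c(100, 100), c(1, 4, 16), seed = 7)
  l2 <- as.vector(zh$levels[[2]]$labels$values)
  l3 <- as.vector(zh$levels[[3]]$labels$values)
  expect_equal(zh$levels[[3]]$n_zones, 16)
  for (z in 1:16)
    expect_length(unique(l2[l3 == z]), 1)  # never straddles a parent
  # every cell labelled at every level
  for (lv in zh$levels)
    expect_true(all(lv$labels$values >= 1))
  # errors
  expect_error(partition_zones(c(10, 10), c(0)), "invalid configuration")
  expect_error(partition_zones(c(10, 10), c(4, 2)), "invalid configuration")
  expect_error(partition_zones(c(4, 4), c(1, 200)), "invalid configuration")
})

test_that("generated scenes satisfy the covariate structure contract", {
  sc <- small_scene(seed = 2)
  dens <- sc$covariates$density$values
  h <- sc$covariates$height$values
  tv <- sc$covariates$types$values
  expect_true(all(dens >= 0 & dens <= 100))
  expect_true(all(h >= 0))
  expect_true(all(h[dens == 0] == 0))                    # no ghost heights
  expect_true(all(tv[dens == 0] == TYPE_CODES[["NONE"]]))# types need buildings
  expect_true(all(tv[dens > 0] != TYPE_CODES[["NONE"]]))
  # height-density correlation within the configured band
  b <- dens > 0
  expect_lt(abs(cor(h[b], dens[b]) - sc$config$height_density_corr), 0.15)
})

test_that("scenes are reproducible and seeds matter", {
  cfg <- scene_config(grid_shape = c(48, 48), n_zones_per_level = c(1, 4),
                      seed = 9)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a$covariates$density$values, b$covariates$density$values)
  expect_identical(a$truth$values, b$truth$values)
  c_ <- generate_landscape(scene_config(grid_shape = c(48, 48),
                                        n_zones_per_level = c(1, 4),
                                        seed = 10))
  expect_false(identical(a$truth$values, c_$truth$values))
})

test_that("census tables are exact aggregates of the integer truth, at every level", {
  for (s in 1:5) {
    sc <- small_scene(seed = s)
    for (nm in names(sc$zones$levels)) {
      lv <- sc$zones$levels[[nm]]
      agg <- oracle_aggregate(sc$truth$values, lv$labels$values, lv$n_zones)
      expect_identical(lv$census, agg)
    }
    # refinement: fine census aggregates exactly to each coarser level
    leaf <- sc$zones$levels[[length(sc$zones$levels)]]
    for (nm in head(names(sc$zones$levels), -1)) {
      lv <- sc$zones$levels[[nm]]
      # map each leaf zone to its parent via any one of its cells
      l_leaf <- as.vector(leaf$labels$values)
      l_par <- as.vector(lv$labels$values)
      parent_of <- l_par[match(seq_len(leaf$n_zones), l_leaf)]
      rolled <- as.vector(tapply(leaf$census, parent_of, sum))
      expect_equal(unname(rolled), lv$census)
    }
  }
})

test_that("noise-free truth equals the floor-area forward model before rounding", {
  sc <- generate_landscape(scene_config(grid_shape = c(64, 64),
                                        n_zones_per_level = c(1, 4, 16),
                                        noise_sd = 0, seed = 4))
  fwd <- bu_population(sc$covariates, sc$region_map, sc$lfa_table,
                       model = sc$config$floor_model)
  expect_equal(sc$truth_raw$values, fwd$values, tolerance = 1e-12)
  # rounding moves no cell by one person or more (largest remainder)
  expect_lt(max(abs(sc$truth$values - fwd$values)), 1)
})

test_that("industrial and lightweight cells carry zero truth population", {
  sc <- small_scene(seed = 3)
  tv <- sc$covariates$types$values
  nonres <- tv == TYPE_CODES[["IC"]] | tv == TYPE_CODES[["LS"]]
  expect_true(all(sc$truth$values[nonres] == 0))
})

test_that("invalid scene configurations are rejected", {
  expect_error(scene_config(n_zones_per_level = c(4, 2)),
               "invalid configuration")
  expect_error(scene_config(grid_shape = c(4, 4),
                            n_zones_per_level = c(1, 64)),
               "invalid configuration")
  expect_error(scene_config(urban_fraction = 1.2), "invalid configuration")
  expect_error(scene_config(height_density_corr = 0), "invalid configuration")
  expect_error(scene_config(noise_sd = -1), "invalid configuration")
})
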