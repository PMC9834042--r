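# one-row landscapes: cells west->east, flow eastward to the outlet
lc_row <- function(classes) {
  matrix(LC_CLASSES[classes], 1, length(classes))
}
row_asset <- function(lc, classes = ASSET_CLASSES) asset_mask(lc, classes)

test_that("retention_ncp: hand-traced line, zero-efficiency, conservation", {
  flow <- line_flow(3)
  lc <- lc_row(c("cropland", "forest", "grassland"))
  asset <- row_asset(lc)
  loads <- matrix(c(10, 0, 0), 1, 3)
  pop <- matrix(c(0, 0, 7), 1, 3)
  dp <- downstream_population(flow, pop)
  lyr <- retention_ncp(loads, flow, lc, c(forest = 0.6), asset, dp,
                       "nitrogen")
  expect_equal(attr(lyr, "retained")[1, 2], 6)       # 10 * 0.6 at forest
  expect_equal(lyr$values[1, 2], 42)                 # 6 retained * 7 people
  expect_equal(attr(lyr, "retained_total") + attr(lyr, "delivered_total"),
               sum(loads), tolerance = 1e-12)
  # zero efficiency: nothing retained, everything delivered
  lyr0 <- retention_ncp(loads, flow, lc, c(forest = 0), asset, dp,
                        "nitrogen")
  expect_true(all(lyr0$values == 0))
  expect_equal(attr(lyr0, "delivered_total"), sum(loads))
  expect_error(retention_ncp(loads, flow, lc, c(forest = 1.2), asset, dp),
               "efficiency")
})

test_that("retention_ncp equals the per-source path-walk oracle", {
  eff <- c(forest = 0.6, wetland = 0.8, grassland = 0.4, sparse = 0.3,
           inland_water = 0.2)
  for (s in 1:5) {
    b <- small_bundle(seed = 40 + s, n = 10)
    flow <- d8_directions(b$elevation_m, b$realm, 2)
    asset <- asset_mask(b$land_cover, NATURAL_CLASSES)
    dp <- downstream_population(flow, b$population)
    lyr <- retention_ncp(b$fertilizer_load, flow, b$land_cover, eff,
                         asset, dp, "nitrogen")
    eff_m <- matrix(0, 10, 10)
    for (cl in names(eff)) eff_m[b$land_cover == LC_CLASSES[[cl]]] <- eff[[cl]]
    eff_m[!asset$is_asset] <- 0
    orc <- oracle_retention(b$fertilizer_load, flow, eff_m)
    expect_equal(attr(lyr, "retained"), orc$retained, tolerance = 1e-9)
    expect_equal(attr(lyr, "delivered_total"), orc$delivered,
                 tolerance = 1e-9)
    expect_equal(attr(lyr, "retained_total") + attr(lyr, "delivered_total"),
                 sum(b$fertilizer_load),
                 tolerance = 1e-9 * sum(b$fertilizer_load))
  }
})

test_that("pollination_ncp: sufficiency, equal credit, degenerate cases", {
  lc <- lc_row(c("forest", "cropland", "forest"))
  asset <- row_asset(lc)
  prod <- matrix(c(0, 100, 0), 1, 3)
  dep <- matrix(0.5, 1, 3)
  lyr <- pollination_ncp(lc, prod, dep, asset, flight_radius_cells = 1)
  expect_equal(as.vector(lyr$values), c(25, 0, 25))  # realized 50 split
  # zero dependency kills the layer
  lyr0 <- pollination_ncp(lc, prod, matrix(0, 1, 3), asset, 1)
  expect_true(all(lyr0$values == 0))
  # no habitat in radius: nothing realized, no credits
  lc2 <- lc_row(c("bare", "cropland", "bare"))
  lyr2 <- pollination_ncp(lc2, prod, dep, row_asset(lc2), 1)
  expect_true(all(lyr2$values == 0))
})

test_that("fodder_ncp applies min(supply, demand) and rescales", {
  lc <- lc_row(c("grassland", "grassland"))
  asset <- asset_mask(lc, c("grassland", "sparse"))
  r1 <- fodder_ncp(matrix(c(5, 2), 1, 2), matrix(c(3, 3), 1, 2), asset,
                   rescale = FALSE)
  expect_equal(as.vector(r1$values), c(3, 2))        # min per branch
  r2 <- fodder_ncp(matrix(c(3, 6), 1, 2), matrix(c(1e9, 1e9), 1, 2),
                   asset)
  expect_equal(as.vector(r2$values), c(0.5, 1.0))    # index by max
  expect_warning(fodder_ncp(matrix(0, 1, 2), matrix(0, 1, 2), asset),
                 "all-zero")
})

test_that("timber/fuelwood: sustainable fraction and strict cutoffs", {
  lc <- lc_row(rep("forest", 4))
  asset <- asset_mask(lc, "forest")
  stock <- matrix(100, 1, 4)
  cover <- matrix(1, 1, 4)
  rate <- matrix(2, 1, 4)                  # 50 years -> fraction 0.02
  pop <- matrix(1000, 1, 4)
  poor <- matrix(100, 1, 4)
  travel <- matrix(c(360, 361, 100, 100), 1, 4)
  slope <- matrix(c(10, 10, 70, 69.999), 1, 4)
  out <- timber_fuelwood_ncp(stock, cover, rate, travel, slope, pop, poor,
                             asset, asset, grid_spec(1, 4))
  com <- attr(out$commercial_timber, "raw")
  expect_equal(com[1, 1], 100 * 1 * 0.02)  # supply = stock*cover/50
  expect_equal(com[1, 2], 0)               # 361 min: beyond 6 h
  expect_equal(com[1, 3], 0)               # slope 70 exactly: excluded
  expect_gt(com[1, 4], 0)                  # 69.999: included
  dom <- attr(out$domestic_timber, "raw")
  expect_true(all((com > 0) + (dom > 0) <= 1))   # mutually exclusive
  expect_gt(dom[1, 2], 0)                  # inaccessible cell -> domestic
  expect_error(
    timber_fuelwood_ncp(stock, cover, rate, travel, slope - 100, pop,
                        poor, asset, asset, grid_spec(1, 4)),
    "negative slope")
})

test_that("flood_ncp: mean of components times people downstream", {
  lc <- lc_row(c("wetland", "grassland"))
  asset <- row_asset(lc)
  dp <- structure(list(grid = grid_spec(1, 2),
                       people_downstream = matrix(c(10, 0), 1, 2)),
                  class = "downstream_population")
  lyr <- flood_ncp(matrix(0.6, 1, 2), matrix(0.3, 1, 2),
                   matrix(0.6, 1, 2), dp, asset)
  expect_equal(lyr$values[1, 1], 5)        # index 0.5 * 10 people
  expect_equal(lyr$values[1, 2], 0)        # nobody downstream
  lyr1 <- flood_ncp(matrix(1, 1, 2), matrix(1, 1, 2), matrix(1, 1, 2),
                    dp, asset)
  expect_equal(lyr1$values[1, 1], 10)      # upper bound = P
  expect_error(flood_ncp(matrix(1.2, 1, 2), matrix(1, 1, 2),
                         matrix(1, 1, 2), dp, asset), "storage")
})

test_that("access_ncp passes through on assets and is monotone in budget", {
  b <- small_bundle(seed = 6, n = 12)
  asset <- asset_mask(b$land_cover, NATURAL_CLASSES)
  pw1 <- population_within(b$friction_min_per_km, b$population, 60,
                           cell_size_km = 2)
  pw2 <- population_within(b$friction_min_per_km, b$population, 120,
                           cell_size_km = 2)
  l1 <- access_ncp(pw1, asset)
  l2 <- access_ncp(pw2, asset)
  expect_equal(l1$values[asset$is_asset][1:5], pw1[asset$is_asset][1:5])
  expect_true(all(l1$values[!asset$is_asset] == 0))
  expect_true(all(l2$values >= l1$values))
})

test_that("fish regression: exact recovery, formula, sampling behaviour", {
  beta <- c(50, 0.8, 12, 3)
  tbl0 <- simulate_fish_basins(12, beta, sigma = 0, seed = 2)
  fit0 <- fit_fish_regression(tbl0)
  expect_equal(unname(fit0$coefficients), beta, tolerance = 1e-8)
  tbl <- simulate_fish_basins(40, beta, sigma = 20, seed = 3)
  fit <- fit_fish_regression(tbl)
  expect_equal(fit$adj_r_squared,
               1 - (1 - fit$r_squared) * (40 - 1) / (40 - 3 - 1))
  expect_error(fit_fish_regression(tbl0[1:3, ]), "at least 5")
  sing <- tbl0
  sing$discharge <- 2 * sing$pop_density
  expect_error(fit_fish_regression(sing), "singular")
})

test_that("riverine_fish_ncp rescales predictions to reported totals", {
  grid <- grid_spec(1, 4)
  lc <- lc_row(c("inland_water", "inland_water", "inland_water",
                 "inland_water"))
  asset <- asset_mask(lc, "inland_water")
  basin_raster <- matrix(c(1L, 1L, 2L, 2L), 1, 4)
  basins <- data.frame(basin_id = 1:2, region = c("A", "A"),
                       pop_density = c(20, 10), discharge = c(0, 0),
                       wetland_pct = c(0, 0))
  # coefficients make predictions 2:1 (intercept 0, slope 1 on density)
  lyr <- riverine_fish_ncp(c(0, 1, 0, 0), basins, basin_raster, asset,
                           c(A = 30), grid)
  cell_km2 <- grid$cell_area_km2
  expect_equal(sum(lyr$values[1, 1:2]) * cell_km2, 20)   # 2/3 of 30
  expect_equal(sum(lyr$values[1, 3:4]) * cell_km2, 10)   # 1/3 of 30
  # one basin per region receives the full total regardless of magnitude
  one <- riverine_fish_ncp(c(0, 1, 0, 0), basins[1, ],
                           matrix(c(1L, 1L, NA, NA), 1, 4), asset,
                           c(A = 7), grid)
  expect_equal(sum(one$values) * cell_km2, 7)
  # negative prediction floors to zero -> whole total goes to basin 1
  neg <- riverine_fish_ncp(c(0, 1, -100, 0),
                           transform(basins, discharge = c(0, 1)),
                           basin_raster, asset, c(A = 30), grid)
  expect_equal(sum(neg$values[1, 1:2]) * cell_km2, 30)
  expect_equal(sum(neg$values[1, 3:4]), 0)
  # region with catch but nothing placeable errors (or skips on request)
  empty_asset <- asset_mask(lc_row(rep("forest", 4)), "inland_water")
  expect_error(riverine_fish_ncp(c(0, 1, 0, 0), basins, basin_raster,
                                 empty_asset, c(A = 30), grid),
               "disaggregation")
})

test_that("coastal_ncp: hand trace, elevation cutoff, validation", {
  # 1 x 4: [marine-habitat, shore, pop, pop]; protective distance 2
  lc <- lc_row(c("marine", "grassland", "urban", "urban"))
  asset <- asset_mask(lc, c("forest", "wetland", "marine"))
  ew <- matrix(c(0, 0.8, 0, 0), 1, 4)   # shore cell baseline exposure
  eh <- matrix(c(0, 0.3, 0, 0), 1, 4)
  pop <- matrix(c(0, 0, 25, 15), 1, 4)
  elev <- matrix(c(-5, 2, 3, 4), 1, 4)
  lyr <- coastal_ncp(eh, ew, 2, pop, elev, asset)
  expect_equal(lyr$values[1, 1], 0.5 * 40)   # only habitat cell in range
  # population above the 10 m strip is not protected
  lyr2 <- coastal_ncp(eh, ew, 2, pop, matrix(c(-5, 2, 12, 12), 1, 4),
                      asset)
  expect_equal(sum(lyr2$values), 0)
  expect_error(coastal_ncp(ew, eh, 2, pop, elev, asset), "exceeds")
})

test_that("marine passthrough masks without transforming", {
  lc <- lc_row(c("marine", "forest", "marine"))
  asset <- asset_mask(lc, "marine")
  vals <- matrix(c(3.2, 9, 1.1), 1, 3)
  lyr <- marine_passthrough(vals, asset, "marine_fish")
  expect_equal(as.vector(lyr$values), c(3.2, 0, 1.1))
  expect_equal(sum(vals) - sum(lyr$values), 9)   # only off-asset dropped
})

test_that("carbon_ncp multiplies stock, vulnerability and area", {
  lc <- lc_row(c("forest", "grassland"))
  asset <- asset_mask(lc, c("forest", "grassland"))
  grid <- grid_spec(1, 2, cell_size_km = 2)     # 4 km2 = 400 ha
  lyr <- carbon_ncp(matrix(c(120, 10), 1, 2),
                    c(forest = 0.5, grassland = 0), lc, asset, grid)
  expect_equal(lyr$values[1, 1], 120 * 0.5 * 400)   # 24,000 tC
  expect_equal(lyr$values[1, 2], 0)
  expect_lte(sum(lyr$values), sum(matrix(c(120, 10), 1, 2)) * 400)
  expect_error(carbon_ncp(matrix(c(120, 10), 1, 2), c(forest = 0.5),
                          lc, asset, grid), "mapping error")
})

test_that("moisture_ncp conserves mass through the kernel", {
  grid <- grid_spec(4, 4)
  lc <- matrix(LC_CLASSES[["forest"]], 4, 4)
  asset <- asset_mask(lc, "forest")
  et <- matrix(runif(16, 400, 900), 4, 4)
  veg <- matrix(0.8, 4, 4)
  ident <- Matrix::Diagonal(16)
  rainfed <- matrix(TRUE, 4, 4)
  lyr <- moisture_ncp(et, ident, rainfed, veg, asset)
  expect_equal(lyr$values, et * veg)     # identity kernel, full mask
  lyr0 <- moisture_ncp(et, ident, matrix(FALSE, 4, 4), veg, asset)
  expect_true(all(lyr0$values == 0))
  k <- moisture_kernel(grid, drift_cells = 1, spread_cells = 1,
                       efficiency = 0.9)
  lyr2 <- moisture_ncp(et, k, rainfed, veg, asset)
  expect_lte(sum(lyr2$values), sum(et * veg) + 1e-9)
  bad <- ident * 1.5
  expect_error(moisture_ncp(et, bad, rainfed, veg, asset), "conservation")
})

test_that("every computed layer is finite, >= 0 and zero off-asset", {
  b <- small_bundle(seed = 2, n = 16)
  cfg <- run_config(generator_config(16, 16), seed = 2,
                    n_species = 0, n_languages = 0)
  nl <- compute_ncp_layers(b, cfg)
  expect_length(nl$layers, 15)
  for (l in nl$layers) {
    expect_true(all(is.finite(l$values)), info = l$name)
    expect_true(all(l$values >= 0), info = l$name)
    expect_true(all(l$values[!l$asset] == 0), info = l$name)
  }
})
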