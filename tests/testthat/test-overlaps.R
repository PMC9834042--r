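test_that("representation targets interpolate log-linearly", {
  rule <- representation_rule("log_linear", 1000, 250000, 1.0, 0.1)
  expect_equal(representation_target(500, rule), 1.0)     # below lower
  expect_equal(representation_target(1000, rule), 1.0)    # at lower
  expect_equal(representation_target(3e5, rule), 0.1)     # above upper
  gm <- sqrt(1000 * 250000)                               # geometric mean
  expect_equal(representation_target(gm, rule), 0.55)
  # continuity and monotone decrease in range size
  areas <- 10^seq(2, 6, length.out = 50)
  tg <- representation_target(areas, rule)
  expect_true(all(diff(tg) <= 1e-12))
  expect_error(representation_target(0, rule), "positive")
})

test_that("minimum-area rule caps at full coverage", {
  rule <- representation_rule("minimum_area", min_area_km2 = 10)
  expect_equal(representation_target(5, rule), 1)         # min(1, 10/5)
  expect_equal(representation_target(100, rule), 0.1)
})

test_that("species_coverage counts met targets with >= at the boundary", {
  grid <- grid_spec(10, 10)
  mk_mask <- function(cells) {
    m <- matrix(FALSE, 10, 10); m[cells] <- TRUE; m
  }
  ov <- list(grid = grid, species = list(
    list(species_id = "in", aoh_mask = mk_mask(1:10),
         range_area_km2 = 40),
    list(species_id = "out", aoh_mask = mk_mask(60:69),
         range_area_km2 = 40),
    list(species_id = "edge", aoh_mask = mk_mask(1:100),
         range_area_km2 = 400)),
    languages = list())
  class(ov) <- "overlay_bundle"
  sol <- mk_mask(1:10)                       # covers 10 cells = 40 km2
  rule <- representation_rule("minimum_area", min_area_km2 = 40)
  res <- species_coverage(ov, sol, rule)
  tbl <- res$table
  expect_true(tbl$met[tbl$species_id == "in"])      # fully inside
  expect_false(tbl$met[tbl$species_id == "out"])    # disjoint
  # 100-cell range, target fraction 0.1 -> 40 km2; exactly 10 cells
  # covered counts as met (>=)
  expect_true(tbl$met[tbl$species_id == "edge"])
  expect_equal(res$n_met, 2L)
})

test_that("language coverage uses partial-intersection semantics", {
  grid <- grid_spec(4, 4)
  mk <- function(cells) { m <- matrix(FALSE, 4, 4); m[cells] <- TRUE; m }
  ov <- structure(list(grid = grid, species = list(), languages = list(
    list(language_id = "inside", extent_mask = mk(1:2)),
    list(language_id = "touch", extent_mask = mk(c(2, 9))),
    list(language_id = "miss", extent_mask = mk(16)))),
    class = "overlay_bundle")
  sol <- mk(1:4)
  lc <- language_coverage(ov, sol)
  expect_equal(lc$n_intersecting, 2L)      # single shared cell counts
  expect_equal(language_coverage(ov, mk(integer(0)))$n_intersecting, 0L)
})

test_that("local/global partition arithmetic is exact", {
  mk <- function(cells) { m <- matrix(FALSE, 10, 10); m[cells] <- TRUE; m }
  local <- mk(1:30)
  global <- mk(7:44)
  part <- partition_local_global(local, global, land_area_km2 = 400,
                                 cell_area_km2 = 4)
  g <- function(x) part$cells[part$component == x]
  expect_equal(g("local_only"), 6L)
  expect_equal(g("global_only"), 14L)
  expect_equal(g("both"), 24L)
  expect_equal(g("union"), 44L)
  expect_equal(g("local_only") + g("global_only") + g("both"), g("union"))
  # identical and disjoint degenerate cases
  same <- partition_local_global(local, local, 400, 4)
  expect_equal(same$cells[same$component == "both"], 30L)
  expect_equal(sum(same$cells[same$component %in%
                                c("local_only", "global_only")]), 0L)
  dis <- partition_local_global(mk(1:5), mk(6:10), 400, 4)
  expect_equal(dis$cells[dis$component == "both"], 0L)
  expect_equal(dis$cells[dis$component == "union"], 10L)
})

test_that("mask_share is the protected-share ratio", {
  mk <- function(cells) { m <- matrix(FALSE, 5, 4); m[cells] <- TRUE; m }
  ref <- mk(1:20)
  expect_equal(mask_share(mk(1:3), ref), 15)     # 3 of 20 cells
  expect_equal(mask_share(mk(1:20), ref), 100)
  expect_equal(mask_share(mk(integer(0)), ref), 0)
  expect_error(mask_share(ref, mk(integer(0))), "empty reference")
})

test_that("coverage statistics grow with the solution mask", {
  b <- make_landscape(generator_config(24, 24), seed = 3)
  ov <- make_overlays(b, 15, 8, seed = 3)
  assets <- which(asset_mask(b$land_cover, NATURAL_CLASSES)$is_asset)
  mk <- function(k) {
    m <- matrix(FALSE, 24, 24); m[assets[seq_len(k)]] <- TRUE; m
  }
  rule <- representation_rule("log_linear", 50, 5000)
  small <- mk(40); large <- mk(length(assets))
  expect_lte(species_coverage(ov, small, rule)$n_met,
             species_coverage(ov, large, rule)$n_met)
  expect_lte(language_coverage(ov, small)$n_intersecting,
             language_coverage(ov, large)$n_intersecting)
})
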