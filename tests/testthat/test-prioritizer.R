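one_ncp_problem <- function(values, target = 0.9) {
  v <- matrix(values, 1)
  rownames(v) <- "ncp1"
  structure(list(region_id = "r", realm = "land",
                 cells = seq_along(values), values = v,
                 totals = sum(values), targets = target,
                 cell_area_km2 = 4, grid = grid_spec(1, length(values))),
            class = "problem_instance")
}

test_that("solve_exact matches hand-enumerated optima", {
  p <- one_ncp_problem(c(10, 5, 1), 0.9)     # need >= 14.4
  s <- solve_exact(p)
  expect_identical(which(s$selected), c(1L, 2L))
  expect_equal(s$area_km2, 8)
  expect_equal(s$optimality_gap, 0)
  # target 1.0 must cover the whole support
  s1 <- solve_exact(p, targets = 1.0)
  expect_identical(which(s1$selected), 1:3)
  # 2 NCP, 3 cells: cell 3 alone gives only 1/10 of each NCP
  v <- t(matrix(c(9, 0, 0, 9, 1, 1), 2, 3, byrow = TRUE))
  v <- matrix(c(9, 0, 1, 0, 9, 1), 2, 3, byrow = TRUE)
  rownames(v) <- c("a", "b")
  p2 <- structure(list(region_id = "r", realm = "land", cells = 1:3,
                       values = v, totals = rowSums(v),
                       targets = c(0.5, 0.5), cell_area_km2 = 4,
                       grid = grid_spec(1, 3)),
                  class = "problem_instance")
  s2 <- solve_exact(p2)
  expect_identical(which(s2$selected), c(1L, 2L))
})

test_that("solve_greedy follows the deficit-capped score and ties", {
  p <- one_ncp_problem(c(10, 5, 1), 0.9)
  g <- solve_greedy(p)
  expect_identical(which(g$selected), c(1L, 2L))   # same as exact here
  # equal values, target 0.5 on 10 cells: first five indices
  pe <- one_ncp_problem(rep(2, 10), 0.5)
  ge <- solve_greedy(pe)
  expect_identical(which(ge$selected), 1:5)
})

test_that("branch-and-bound equals enumeration beyond trivial sizes", {
  for (s in 1:10) {
    p <- random_problem(n = 16, m = 3, seed = 900 + s)
    need <- 0.9 * p$totals
    enum <- critnat:::cpp_cover_enumerate(p$values, need)
    bnb <- critnat:::cpp_cover_bnb(p$values, need, integer(0))
    expect_equal(length(bnb), length(enum))
  }
})

test_that("greedy stays within the multicover approximation factor", {
  worst <- 0
  for (s in 1:25) {
    n <- sample(10:16, 1)
    p <- random_problem(n = n, m = 3, seed = 1200 + s)
    t <- sample(c(0.5, 0.9, 1.0), 1)
    e <- solve_exact(p, targets = t)
    g <- solve_greedy(p, targets = t)
    expect_true(all(g$achieved >= t - 1e-9))
    if (sum(e$selected) > 0) {
      ratio <- sum(g$selected) / sum(e$selected)
      worst <- max(worst, ratio)
      expect_lte(ratio, log(3 * n) + 1)
    }
  }
  # report-style check: greedy never catastrophically worse on these sizes
  expect_lte(worst, log(3 * 16) + 1)
})

test_that("accumulation curve: anchors and monotonicity", {
  p <- one_ncp_problem(c(9, 1))
  cv <- accumulation_curve(list(p), c(0, 0.9, 1.0))
  expect_equal(cv$aggregated$area_km2, c(0, 4, 8))   # 0, 1, 2 cells
  for (s in 1:20) {
    p2 <- random_problem(n = sample(8:14, 1), m = sample(1:3, 1),
                         seed = 1500 + s)
    cv2 <- accumulation_curve(list(p2), seq(0, 1, 0.25))
    expect_true(all(diff(cv2$aggregated$area_km2) >= 0))
    expect_equal(cv2$aggregated$area_km2[1], 0)
  }
})

test_that("concentration: unequal values need less than proportional area", {
  p <- one_ncp_problem(c(40, 25, 15, 9, 5, 3, 2, 1), 0.9)
  a90 <- solve_exact(p, targets = 0.9)$area_km2
  a100 <- solve_exact(p, targets = 1.0)$area_km2
  expect_lt(a90, 0.9 * a100)
})

test_that("build_problems partitions cells by region and pools globally", {
  b <- small_bundle(seed = 8, n = 16)
  cfg <- run_config(generator_config(16, 16), seed = 8, n_species = 0,
                    n_languages = 0)
  nl <- compute_ncp_layers(b, cfg)
  probs <- build_problems(nl$layers, b$region_id, b$realm,
                          nl$aux$asset_all, "country", "land", 0.9,
                          b$grid)
  land_assets <- which(nl$aux$asset_all$is_asset & b$realm == 1L &
                         !is.na(b$region_id))
  got <- sort(unlist(lapply(probs, `[[`, "cells")))
  expect_identical(got, land_assets)
  expect_gt(length(probs), 1)
  pg <- build_problems(nl$layers, b$region_id, b$realm, nl$aux$asset_all,
                       "global", "land", 0.9, b$grid)
  expect_length(pg, 1)
  expect_true(all(rownames(pg[[1]]$values) %in%
                    ncp_layer_names()$global))
  # overlapping-claim cells (NA region) are excluded from national solves
  rid <- b$region_id
  rid[which(nl$aux$asset_all$is_asset & b$realm == 1L)[1:5]] <- NA
  probs2 <- build_problems(nl$layers, rid, b$realm, nl$aux$asset_all,
                           "country", "land", 0.9, b$grid)
  got2 <- unlist(lapply(probs2, `[[`, "cells"))
  expect_false(any(
    which(nl$aux$asset_all$is_asset & b$realm == 1L)[1:5] %in% got2))
})

test_that("audit recomputes achievement from the layers themselves", {
  b <- small_bundle(seed = 8, n = 16)
  cfg <- run_config(generator_config(16, 16), seed = 8, n_species = 0,
                    n_languages = 0)
  nl <- compute_ncp_layers(b, cfg)
  probs <- build_problems(nl$layers, b$region_id, b$realm,
                          nl$aux$asset_all, "country", "land", 0.9,
                          b$grid)
  for (p in probs) {
    s <- solve_greedy(p)
    aud <- audit_solution(s, nl$layers)
    expect_true(aud$pass)
  }
})

test_that("drop-one: redundant layers change nothing, removal never
           increases exact area", {
  for (s in 1:5) {
    p <- random_problem(n = 12, m = 3, seed = 1700 + s)
    dup <- p
    dup$values <- rbind(dup$values, dup$values[3, , drop = FALSE])
    rownames(dup$values) <- c("ncp1", "ncp2", "ncp3", "ncp3_copy")
    dup$totals <- rowSums(dup$values)
    dup$targets <- rep(0.9, 4)
    tab <- drop_one_sensitivity(list(dup), target = 0.9, solver = "exact")
    expect_equal(tab$delta_area_pct[tab$dropped_ncp == "ncp3"], 0)
    expect_true(all(tab$delta_area_pct <= 1e-9))
    expect_true(all(tab$shared_area_fraction >= 0 &
                      tab$shared_area_fraction <= 1))
    expect_gte(attr(tab, "all_shared_fraction"), 0)
  }
})

test_that("solution_overlap reports directional and all-shared overlap", {
  a <- matrix(FALSE, 2, 4); a[1, 1:2] <- TRUE
  b <- matrix(FALSE, 2, 4); b[1, 1:4] <- TRUE
  ov <- solution_overlap(list(A = a, B = b))
  expect_equal(ov$pairwise_pct["A", "B"], 100)   # A entirely inside B
  expect_equal(ov$pairwise_pct["B", "A"], 50)
  expect_equal(ov$all_shared_fraction, 0.5)
  same <- solution_overlap(list(x = a, y = a))
  expect_true(all(same$pairwise_pct == 100))
  expect_equal(same$all_shared_fraction, 1)
  d <- matrix(FALSE, 2, 4); d[2, 1] <- TRUE
  dis <- solution_overlap(list(a = a, d = d))
  expect_equal(dis$pairwise_pct["a", "d"], 0)
  expect_equal(dis$all_shared_fraction, 0)
})

test_that("oversized instances are directed to the greedy surrogate", {
  p <- random_problem(n = 30, m = 2, seed = 42)
  expect_error(solve_exact(p, exact_cap = 25), "size error")
  g <- solve_greedy(p)
  expect_true(all(g$achieved >= 0.9 - 1e-9))
})
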