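test_that("fill_pits: identity on draining DEMs, spill+epsilon on pits", {
  # already draining: strictly descending to the edges
  elev <- matrix(c(3, 2, 1), 1, 3)
  land <- matrix(TRUE, 1, 3)
  expect_identical(fill_pits(elev, land), elev)
  # centre pit between two edge outlets rises to min neighbour + eps
  pit <- matrix(c(1, 0, 1), 1, 3)
  filled <- fill_pits(pit, land, eps = 1e-6)
  expect_equal(filled[1, 2], 1 + 1e-6)
  expect_identical(filled[1, c(1, 3)], c(1, 1))
  expect_error(fill_pits(matrix(0, 2, 2), matrix(FALSE, 2, 2)),
               "empty-domain")
})

test_that("filled random DEMs always drain (property, 20 seeds)", {
  for (s in 1:20) {
    dem <- random_dem(8, 8, seed = 100 + s)
    expect_true(all(dem$elev >= -5))
    flow <- d8_directions(dem$elev, dem$realm)
    n_land <- sum(dem$realm == 1L)
    ord <- critnat:::topological_order(flow)   # errors on any cycle
    expect_length(ord, n_land)
    # descent is strict along every flow edge
    to <- critnat:::downstream_index(flow)
    from <- which(!is.na(to))
    expect_true(all(dem$elev[from] > dem$elev[to[from]]))
  }
})

test_that("d8_directions: steepest descent, outlets and tie-breaks", {
  land <- matrix(TRUE, 1, 3)
  f <- d8_directions(matrix(c(3, 2, 1), 1, 3), land)
  expect_identical(as.vector(f$direction), c(1L, 1L, 0L))  # E, E, outlet
  # marine-adjacent cell with no lower land neighbour is an outlet
  f2 <- d8_directions(matrix(c(3, 2, 1, -5), 1, 4),
                      matrix(c(1L, 1L, 1L, 2L), 1, 4))
  expect_identical(as.vector(f2$direction), c(1L, 1L, 0L, NA))
  # equal drops east and north: code order picks E
  elev <- matrix(2, 3, 3)
  elev[2, 2] <- 1; elev[2, 3] <- 0; elev[1, 2] <- 0
  f3 <- d8_directions(elev, matrix(TRUE, 3, 3))
  expect_identical(f3$direction[2, 2], 1L)                 # E beats N
  # diagonal chosen only when drop/sqrt(2) beats cardinal drops
  e4 <- matrix(c(4, 2, 3, 1), 2, 2)   # [[4,3],[2,1]] row-wise
  f4 <- d8_directions(e4, matrix(TRUE, 2, 2))
  expect_identical(f4$direction[1, 1], 2L)                 # SE: 3/sqrt2 > 2
})

test_that("downstream_population matches the path-trace definition", {
  flow <- line_flow(3)
  pop <- matrix(c(0, 4, 7), 1, 3)
  dp <- downstream_population(flow, pop)
  expect_equal(as.vector(dp$people_downstream), c(11, 7, 0))
  dp0 <- downstream_population(flow, matrix(0, 1, 3))
  expect_true(all(dp0$people_downstream == 0))
  # own-cell inclusion switch
  dpi <- downstream_population(flow, pop, include_self = TRUE)
  expect_equal(as.vector(dpi$people_downstream), c(11, 11, 7))
})

test_that("hydrology equals brute-force oracles on random instances", {
  for (s in 1:20) {
    nr <- sample(8:10, 1)
    dem <- random_dem(nr, nr, seed = 300 + s)
    flow <- d8_directions(dem$elev, dem$realm)
    pop <- matrix(rpois(nr * nr, 5), nr, nr)
    pop[dem$realm == 2L] <- 0
    dp <- downstream_population(flow, pop)
    expect_equal(dp$people_downstream, oracle_downstream_pop(flow, pop))
    expect_equal(flow_accumulation(flow), oracle_accumulation(flow))
    # conservation: population accumulated at outlets = population on land
    acc_pop <- flow_accumulation(flow, pop)
    outlets <- !is.na(flow$direction) & flow$direction == 0L
    expect_equal(sum(acc_pop[outlets]), sum(pop[dem$realm == 1L]),
                 tolerance = 1e-9)
  }
})

test_that("cycle detection raises a routing error", {
  bad <- structure(list(grid = grid_spec(1, 2),
                        direction = matrix(c(1L, 5L), 1, 2),
                        land = matrix(TRUE, 1, 2)),
                   class = "flow_direction")
  expect_error(critnat:::topological_order(bad), "cycle")
})

test_that("floodplain mask thresholds and buffers correctly", {
  expect_error(floodplain_mask(line_flow(5), -1), "negative threshold")
  # threshold 1 marks every land cell (accumulation includes self)
  expect_true(all(floodplain_mask(line_flow(5), 1, buffer_km = 0)))
  # 1 x 5 line: accumulation counts 1..5 (self included), so threshold 3
  # marks the three most-downstream cells under the >= contract
  fp <- floodplain_mask(line_flow(5), 3, buffer_km = 0)
  expect_identical(as.vector(fp), c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # 10 km buffer on 2-km cells = 5-cell radius, vs distance oracle
  dem <- random_dem(9, 9, seed = 42)
  flow <- d8_directions(dem$elev, dem$realm)
  core <- flow_accumulation(flow) >= 8
  core[is.na(core)] <- FALSE
  fp2 <- floodplain_mask(flow, 8, buffer_km = 10)
  dist_oracle <- matrix(Inf, 9, 9)
  for (cell in which(core)) {
    r0 <- (cell - 1) %% 9 + 1; c0 <- (cell - 1) %/% 9 + 1
    for (x in seq_len(81)) {
      r <- (x - 1) %% 9 + 1; c <- (x - 1) %/% 9 + 1
      d <- 2 * sqrt((r - r0)^2 + (c - c0)^2)   # km on 2-km cells
      dist_oracle[x] <- min(dist_oracle[x], d)
    }
  }
  expect_identical(fp2, dist_oracle <= 10 + 1e-9)
})
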