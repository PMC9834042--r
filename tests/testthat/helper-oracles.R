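# Independent oracles and tiny fixture builders. Each oracle is a direct,
# brute-force transcription of the definition it checks, deliberately
# sharing no code with the implementation paths under test.

# --- flow fixtures ----------------------------------------------------

# 1 x n west-to-east line: directions E, E, ..., outlet
line_flow <- function(n) {
  dir <- matrix(c(rep(1L, n - 1), 0L), 1, n)
  structure(list(grid = grid_spec(1, n), direction = dir,
                 land = matrix(TRUE, 1, n)),
            class = "flow_direction")
}

# random pit-filled DEM fixture with a marine fringe on the east edge
random_dem <- function(nr, nc, seed, marine_col = TRUE) {
  set.seed(seed)
  realm <- matrix(1L, nr, nc)
  if (marine_col) realm[, nc] <- 2L
  elev <- matrix(runif(nr * nc, 0, 50), nr, nc)
  elev[realm == 2L] <- -5
  filled <- fill_pits(elev, realm)
  list(elev = filled, realm = realm)
}

# --- hydrology oracles ------------------------------------------------

# walk the D8 path from each cell; sum population strictly downstream
oracle_downstream_pop <- function(flow, population) {
  to <- critnat:::downstream_index(flow)
  out <- matrix(NA_real_, nrow(flow$direction), ncol(flow$direction))
  for (v in which(!is.na(flow$direction))) {
    s <- 0
    w <- to[v]
    while (!is.na(w)) {
      s <- s + population[w]
      w <- to[w]
    }
    out[v] <- s
  }
  out
}

# per-cell count of cells whose path passes through it (including self)
oracle_accumulation <- function(flow) {
  to <- critnat:::downstream_index(flow)
  out <- matrix(NA_real_, nrow(flow$direction), ncol(flow$direction))
  out[!is.na(flow$direction)] <- 0
  for (v in which(!is.na(flow$direction))) {
    w <- v
    while (!is.na(w)) {
      out[w] <- out[w] + 1
      w <- to[w]
    }
  }
  out
}

# per-source path walk of the retention model
oracle_retention <- function(loads, flow, eff_matrix) {
  to <- critnat:::downstream_index(flow)
  retained <- matrix(0, nrow(loads), ncol(loads))
  delivered <- 0
  for (src in which(loads > 0)) {
    mass <- loads[src]
    w <- to[src]
    while (!is.na(w)) {
      kept <- mass * eff_matrix[w]
      retained[w] <- retained[w] + kept
      mass <- mass - kept
      w <- to[w]
    }
    delivered <- delivered + mass
  }
  list(retained = retained, delivered = delivered)
}

# --- travel oracle: Bellman-Ford-style relaxation to fixpoint ---------

oracle_travel <- function(friction, sources, cell_km) {
  nr <- nrow(friction); nc <- ncol(friction)
  d <- matrix(Inf, nr, nc)
  d[sources] <- 0
  grid <- grid_spec(nr, nc, cell_km)
  repeat {
    changed <- FALSE
    for (cell in seq_len(nr * nc)) {
      for (k in seq_along(critnat:::D8_DR)) {
        nb <- critnat:::neighbor_index(cell, k, grid)
        if (is.na(nb)) next
        w <- 0.5 * (friction[cell] + friction[nb]) * cell_km *
          critnat:::D8_DIST[k]
        if (d[nb] + w < d[cell] - 1e-12) {
          d[cell] <- d[nb] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d
}

# --- optimizer oracle: chunked bitmask enumeration --------------------

# minimum number of columns of v whose row sums meet `need`
oracle_min_cover <- function(v, need) {
  n <- ncol(v); m <- nrow(v)
  tol <- 1e-9 * pmax(1, need)
  if (all(need <= tol)) return(0L)
  best <- Inf
  chunk <- 2^16
  total <- 2^n
  for (start in seq(0, total - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, total - 1)
    bits <- matrix(0, length(idx), n)
    for (j in seq_len(n)) bits[, j] <- (idx %/% 2^(j - 1)) %% 2
    sums <- bits %*% t(v)
    ok <- sums >= matrix(need - tol, length(idx), m, byrow = TRUE)
    feas <- rowSums(ok) == m
    if (any(feas)) {
      best <- min(best, min(rowSums(bits[feas, , drop = FALSE])))
    }
  }
  as.integer(best)
}

# random multicover instance as a problem object
random_problem <- function(n, m, seed, zero_frac = 0.3) {
  set.seed(seed)
  v <- matrix(runif(m * n, 0, 10), m, n)
  v[runif(m * n) < zero_frac] <- 0
  # guarantee full support so every target <= 1 is feasible
  for (i in seq_len(m)) if (sum(v[i, ]) == 0) v[i, 1] <- 1
  rownames(v) <- paste0("ncp", seq_len(m))
  structure(list(region_id = "r1", realm = "land", cells = seq_len(n),
                 values = v, totals = rowSums(v),
                 targets = rep(0.9, m), cell_area_km2 = 4,
                 grid = grid_spec(1, n)),
            class = "problem_instance")
}

# small landscape shared by several suites (rebuilt per call; cheap)
small_bundle <- function(seed = 3, n = 20) {
  make_landscape(generator_config(n, n), seed = seed)
}
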