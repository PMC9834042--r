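#' Build prioritization problem instances from NCP layers
#'
#' Country scale produces one instance per planning region and realm; the
#' twelve local NCP (thirteen layers) are optimized within each country,
#' while the two global NCP are pooled into a single global instance.
#' Cells are restricted to natural-asset cells of the matching realm;
#' cells with no region id (overlapping claims) are excluded from national
#' instances. Layers whose total over an instance is zero impose no
#' constraint and are dropped from it.
#'
#' @param layers named list of `ncp_layer`s sharing one grid.
#' @param region_id integer region matrix (NA = overlapping claim).
#' @param realm realm matrix (1 = land, 2 = eez).
#' @param asset an [asset_mask()] delimiting selectable cells.
#' @param scale `"country"` or `"global"`.
#' @param realms which realms to build instances for.
#' @param targets proportional target in `[0, 1]` recorded on each
#'   instance (scalar, recycled over layers).
#' @param grid a [grid_spec()].
#' @return list of `problem_instance` objects.
#' @export
build_problems <- function(layers, region_id, realm, asset,
                           scale = c("country", "global"),
                           realms = c("land", "eez"), targets = 0.9,
                           grid) {
  scale <- match.arg(scale)
  sel_names <- ncp_layer_names()[[if (scale == "country") "local"
                                  else "global"]]
  layers <- layers[intersect(sel_names, names(layers))]
  out <- list()
  for (rl in realms) {
    rl_code <- REALM_CODES[[rl]]
    use <- vapply(layers, function(l)
      l$realm %in% c("both", if (rl == "land") "land" else "marine"),
      logical(1))
    lyr <- layers[use]
    if (!length(lyr)) next
    base_cells <- asset$is_asset & realm == rl_code
    groups <- if (scale == "country") {
      ids <- sort(unique(region_id[base_cells & !is.na(region_id)]))
      lapply(ids, function(id)
        which(base_cells & !is.na(region_id) & region_id == id))
    } else {
      list(which(base_cells))
    }
    gids <- if (scale == "country") {
      sort(unique(region_id[base_cells & !is.na(region_id)]))
    } else "global"
    for (gi in seq_along(groups)) {
      cells <- groups[[gi]]
      if (!length(cells)) next
      vals <- do.call(rbind, lapply(lyr, function(l) l$values[cells]))
      rownames(vals) <- names(lyr)
      totals <- rowSums(vals)
      keep <- totals > 0
      if (!any(keep)) next
      out[[length(out) + 1]] <- structure(list(
        region_id = gids[[gi]], realm = rl, cells = cells,
        values = vals[keep, , drop = FALSE], totals = totals[keep],
        targets = rep(targets, sum(keep)),
        cell_area_km2 = grid$cell_area_km2, grid = grid),
        class = "problem_instance")
    }
  }
  out
}

#' @export
print.problem_instance <- function(x, ...) {
  cat(sprintf("<problem_instance> region %s (%s): %d cells, %d NCP\n",
              x$region_id, x$realm, length(x$cells), nrow(x$values)))
  invisible(x)
}

new_solution <- function(problem, sel_idx, solver, gap = 0) {
  sel <- logical(length(problem$cells))
  sel[sel_idx] <- TRUE
  achieved <- as.vector(problem$values %*% sel) / problem$totals
  structure(list(region_id = problem$region_id, realm = problem$realm,
                 cells = problem$cells, selected = sel,
                 selected_cells = problem$cells[sel],
                 area_km2 = sum(sel) * problem$cell_area_km2,
                 achieved = setNames(achieved, rownames(problem$values)),
                 targets = problem$targets, solver = solver,
                 optimality_gap = gap, grid = problem$grid),
            class = "cna_solution")
}

#' @export
print.cna_solution <- function(x, ...) {
  cat(sprintf("<solution> region %s (%s): %d cells (%.4g km2), %s\n",
              x$region_id, x$realm, sum(x$selected), x$area_km2, x$solver))
  invisible(x)
}

#' Exact minimum-area solve
#'
#' Minimizes the number of selected cells subject to achieving
#' `targets[i] * totals[i]` for every NCP. Instances with at most 20 cells
#' are solved by exhaustive subset enumeration with a deterministic
#' lexicographic tie-break among optima; larger instances (up to
#' `exact_cap`) by branch and bound seeded with the greedy incumbent.
#'
#' @param problem a `problem_instance`.
#' @param targets proportional targets (scalar or per retained layer);
#'   defaults to the instance's recorded targets.
#' @param exact_cap largest instance the exact path accepts.
#' @return a solution object (`solver = "exact"`, `optimality_gap = 0`).
#' @export
solve_exact <- function(problem, targets = NULL, exact_cap = 200) {
  tg <- prep_targets(problem, targets)
  n <- length(problem$cells)
  need <- tg * problem$totals
  if (n <= 20) {
    sel_idx <- cpp_cover_enumerate(problem$values, need)
  } else if (n <= exact_cap) {
    greedy <- solve_greedy(problem, targets = tg)
    sel_idx <- cpp_cover_bnb(problem$values, need,
                             which(greedy$selected))
  } else {
    stop("size error: ", n, " cells exceeds exact-solver cap ", exact_cap,
         "; use solve_greedy()")
  }
  new_solution(problem, sel_idx, "exact", gap = 0)
}

prep_targets <- function(problem, targets) {
  tg <- if (is.null(targets)) problem$targets else targets
  if (length(tg) == 1) tg <- rep(tg, nrow(problem$values))
  if (any(tg < 0 | tg > 1)) stop("targets must lie in [0, 1]")
  tg
}

#' Greedy minimum-area solve
#'
#' Iteratively selects the cell with the largest total deficit-capped,
#' total-normalized contribution `sum_i min(v[i][x], deficit_i) / T[i]`,
#' ties broken by lowest cell index; stops when every target is met.
#' Feasible by construction for targets <= 1; the scalable surrogate for
#' instances beyond the exact cap.
#'
#' @inheritParams solve_exact
#' @return a solution object (`solver = "greedy"`, gap unknown, recorded
#'   as `NA`).
#' @export
solve_greedy <- function(problem, targets = NULL) {
  tg <- prep_targets(problem, targets)
  v <- problem$values
  totals <- problem$totals
  need <- tg * totals
  tol <- 1e-9 * pmax(1, need)
  deficit <- need
  n <- ncol(v)
  selected <- logical(n)
  while (any(deficit > tol)) {
    score <- colSums(pmin(v, deficit) / totals)
    score[selected] <- -Inf
    pick <- which.max(score)   # which.max returns the first (lowest) index
    if (!is.finite(score[pick]) || score[pick] <= 0) {
      stop("solver error: no cell can reduce the remaining deficit")
    }
    selected[pick] <- TRUE
    deficit <- pmax(0, deficit - v[, pick])
  }
  new_solution(problem, which(selected), "greedy", gap = NA_real_)
}

#' Solve with the configured policy
#'
#' Exact when the instance is at most `exact_cap` cells, greedy otherwise;
#' the policy the full pipeline applies everywhere.
#'
#' @inheritParams solve_exact
#' @param exact_cap exact-path size cap.
#' @return a solution object.
#' @export
solve_auto <- function(problem, targets = NULL, exact_cap = 20) {
  if (length(problem$cells) <= exact_cap) {
    solve_exact(problem, targets, exact_cap = max(exact_cap, 20))
  } else {
    solve_greedy(problem, targets)
  }
}

#' Independent feasibility audit of a solution
#'
#' Recomputes achieved fractions directly from the NCP layer rasters
#' (not from the problem's value matrix) and checks `achieved >= target`
#' for every constrained NCP.
#'
#' @param solution a solution object.
#' @param layers the named list of `ncp_layer`s the problem was built from.
#' @return list with `achieved`, `targets`, `pass` (logical scalar).
#' @export
audit_solution <- function(solution, layers) {
  nms <- names(solution$achieved)
  achieved <- setNames(numeric(length(nms)), nms)
  for (nm in nms) {
    vals <- layers[[nm]]$values
    tot <- sum(vals[solution$cells])
    achieved[nm] <- if (tot > 0) sum(vals[solution$cells[solution$selected]]) / tot
    else 1
  }
  tg <- solution$targets
  pass <- all(achieved >= tg - 1e-9)
  list(achieved = achieved, targets = tg, pass = pass)
}

#' NCP accumulation curve
#'
#' For each target level every regional problem is re-solved (same solver
#' policy) and the selected areas summed; the aggregated curve is the
#' per-level sum across regions, i.e. the total area required to maintain
#' that level of every NCP in every region.
#'
#' @param problems list of `problem_instance`s.
#' @param targets_grid sorted vector of target levels in `[0, 1]`
#'   (default 5% steps from 5% to 100%).
#' @param solver `"auto"`, `"exact"` or `"greedy"`.
#' @param exact_cap size cap for the exact path.
#' @return object of class `accumulation_curve`: list with data frames
#'   `per_region` and `aggregated` (`target_level`, `area_km2`,
#'   `area_fraction_of_assets`).
#' @export
accumulation_curve <- function(problems, targets_grid = seq(0.05, 1, 0.05),
                               solver = "auto", exact_cap = 20) {
  if (is.unsorted(targets_grid) || any(targets_grid < 0 | targets_grid > 1)) {
    stop("targets_grid must be sorted within [0, 1]")
  }
  solve_one <- function(p, t) switch(solver,
    auto = solve_auto(p, t, exact_cap),
    exact = solve_exact(p, t, max(exact_cap, 200)),
    greedy = solve_greedy(p, t))
  rows <- list()
  for (p in problems) {
    assets_km2 <- length(p$cells) * p$cell_area_km2
    for (t in targets_grid) {
      s <- solve_one(p, t)
      rows[[length(rows) + 1]] <- data.frame(
        region = as.character(p$region_id), realm = p$realm,
        target_level = t, area_km2 = s$area_km2,
        area_fraction_of_assets = s$area_km2 / assets_km2)
    }
  }
  per_region <- do.call(rbind, rows)
  agg <- stats::aggregate(area_km2 ~ target_level, per_region, sum)
  total_assets <- sum(vapply(problems, function(p)
    length(p$cells) * p$cell_area_km2, numeric(1)))
  agg$area_fraction_of_assets <- agg$area_km2 / total_assets
  structure(list(per_region = per_region, aggregated = agg),
            class = "accumulation_curve")
}

drop_layer <- function(problem, name) {
  keep <- setdiff(rownames(problem$values), name)
  if (length(keep) == nrow(problem$values)) return(problem)
  problem$values <- problem$values[keep, , drop = FALSE]
  problem$totals <- problem$totals[keep]
  problem$targets <- rep(problem$targets[1], length(keep))
  problem
}

#' Drop-one-NCP sensitivity analysis
#'
#' Re-solves every regional problem with each NCP excluded in turn and
#' reports the percent change in aggregate area relative to the full
#' solution, the fraction of the full solution's area shared with each
#' reduced solution, and (as attribute `all_shared_fraction`) the fraction
#' of the full solution present in every reduced solution.
#'
#' @param problems list of `problem_instance`s (>= 2 layers overall).
#' @param target proportional target applied to all layers.
#' @param solver,exact_cap solver policy (see [accumulation_curve()]).
#' @return data frame: `dropped_ncp`, `area_km2`, `delta_area_pct`,
#'   `shared_area_fraction`.
#' @export
drop_one_sensitivity <- function(problems, target = 0.9, solver = "auto",
                                 exact_cap = 20) {
  all_names <- unique(unlist(lapply(problems, function(p)
    rownames(p$values))))
  if (length(all_names) < 2) stop("need at least 2 NCP layers")
  solve_one <- function(p, t) switch(solver,
    auto = solve_auto(p, t, exact_cap),
    exact = solve_exact(p, t, max(exact_cap, 200)),
    greedy = solve_greedy(p, t))
  full <- lapply(problems, solve_one, t = target)
  full_cells <- sort(unlist(lapply(full, function(s) s$selected_cells)))
  full_area <- sum(vapply(full, function(s) s$area_km2, numeric(1)))
  rows <- list()
  in_all <- rep(TRUE, length(full_cells))
  for (nm in all_names) {
    red <- list()
    for (p in problems) {
      pr <- drop_layer(p, nm)
      if (nrow(pr$values) == 0) next
      red[[length(red) + 1]] <- solve_one(pr, target)
    }
    red_cells <- sort(unlist(lapply(red, function(s) s$selected_cells)))
    red_area <- sum(vapply(red, function(s) s$area_km2, numeric(1)))
    shared <- if (length(full_cells))
      mean(full_cells %in% red_cells) else 0
    in_all <- in_all & (full_cells %in% red_cells)
    rows[[length(rows) + 1]] <- data.frame(
      dropped_ncp = nm, area_km2 = red_area,
      delta_area_pct = 100 * (red_area - full_area) / full_area,
      shared_area_fraction = shared)
  }
  out <- do.call(rbind, rows)
  attr(out, "all_shared_fraction") <-
    if (length(full_cells)) mean(in_all) else 0
  attr(out, "full_area_km2") <- full_area
  out
}

#' Area sharing between solutions
#'
#' Directional pairwise shared percentages (intersection area over the
#' subject solution's area) and the all-shared fraction (the share of the
#' union contained in every solution).
#'
#' @param solutions named list of logical matrices (or solution objects on
#'   a common grid).
#' @return list with `pairwise_pct` (matrix, rows = subject) and
#'   `all_shared_fraction`.
#' @export
solution_overlap <- function(solutions) {
  masks <- lapply(solutions, function(s) {
    if (inherits(s, "cna_solution")) solution_to_mask(s, s$grid)
    else s == TRUE
  })
  k <- length(masks)
  nm <- names(masks)
  if (is.null(nm)) nm <- paste0("s", seq_len(k))
  pw <- matrix(0, k, k, dimnames = list(nm, nm))
  for (a in seq_len(k)) {
    na_ <- sum(masks[[a]])
    if (na_ == 0) {
      warning("empty solution: ", nm[a])
      next
    }
    for (b in seq_len(k)) {
      pw[a, b] <- 100 * sum(masks[[a]] & masks[[b]]) / na_
    }
  }
  uni <- Reduce(`|`, masks)
  inter <- Reduce(`&`, masks)
  list(pairwise_pct = pw,
       all_shared_fraction = if (sum(uni) > 0) sum(inter) / sum(uni) else 0)
}

#' Rasterize a solution to a logical grid mask
#'
#' @param solution a solution object.
#' @param grid a [grid_spec()].
#' @return logical matrix with selected cells TRUE.
#' @export
solution_to_mask <- function(solution, grid) {
  m <- matrix(FALSE, grid$n_rows, grid$n_cols)
  m[solution$selected_cells] <- TRUE
  m
}
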