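#' Least-cost travel time from source cells
#'
#' Exact shortest-path minutes over a friction surface. The cost of moving
#' between adjacent cells is the mean of the two cells' friction (min/km)
#' times the step length (cell size, x sqrt(2) for diagonals); this
#' mid-point rule makes travel symmetric.
#'
#' @param friction_min_per_km friction matrix (> 0 everywhere).
#' @param sources logical matrix of source cells (>= 1 TRUE).
#' @param cell_size_km cell edge length in km.
#' @return object of class `travel_field`: list with `grid`, `minutes`
#'   (0 on sources, `Inf` where unreachable) and `sources`.
#' @export
travel_time <- function(friction_min_per_km, sources, cell_size_km = 2) {
  if (!any(sources)) stop("parameter error: no source cells")
  if (any(friction_min_per_km <= 0)) {
    stop("parameter error: non-positive friction")
  }
  minutes <- cpp_travel_time(friction_min_per_km, sources, cell_size_km)
  structure(list(grid = grid_spec(nrow(minutes), ncol(minutes),
                                  cell_size_km),
                 minutes = minutes, sources = sources),
            class = "travel_field")
}

#' Population within a travel-time budget of every cell
#'
#' For each target cell `t`, the total population over cells `p` whose
#' travel time to `t` is at most `max_minutes`. Because the mid-point edge
#' cost is symmetric, the field is computed by truncated expansions from
#' the populated cells, which must equal the per-target definition exactly.
#'
#' @param friction_min_per_km friction matrix (> 0).
#' @param population population matrix (>= 0).
#' @param max_minutes travel-time budget (> 0); 60 by default (1 h), 360
#'   for the 6-h sensitivity variant.
#' @param targets optional logical matrix; values are reported on all cells
#'   but masked to `NA` off-target when supplied.
#' @param cell_size_km cell edge length in km.
#' @return matrix of reachable population.
#' @export
population_within <- function(friction_min_per_km, population,
                              max_minutes = 60, targets = NULL,
                              cell_size_km = 2) {
  if (max_minutes <= 0) stop("parameter error: max_minutes must be > 0")
  if (any(friction_min_per_km <= 0)) {
    stop("parameter error: non-positive friction")
  }
  out <- cpp_population_within(friction_min_per_km, population,
                               max_minutes, cell_size_km)
  if (!is.null(targets)) out[!targets] <- NA_real_
  out
}

#' Detect population centres above a size threshold
#'
#' Connected components (8-neighbourhood) of urban cells whose summed
#' population exceeds `min_pop` (default 50,000 persons, the commercial
#' timber accessibility threshold).
#'
#' @param land_cover land-cover matrix coded by [LC_CLASSES].
#' @param population population matrix.
#' @param min_pop component population threshold (strict `>`).
#' @return logical matrix marking the cells of qualifying centres.
#' @export
detect_population_centres <- function(land_cover, population,
                                      min_pop = 5e4) {
  urban <- land_cover == LC_CLASSES[["urban"]]
  lab <- label_components(urban)
  centres <- matrix(FALSE, nrow(land_cover), ncol(land_cover))
  for (id in setdiff(unique(as.vector(lab)), 0L)) {
    comp <- lab == id
    if (sum(population[comp]) > min_pop) centres <- centres | comp
  }
  centres
}
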