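# mark cells strictly downstream of any TRUE cell in `origin`
downstream_of <- function(flow, origin) {
  ord <- topological_order(flow)
  to <- downstream_index(flow)
  mark <- logical(length(to))
  for (v in ord) {               # upstream before downstream
    w <- to[v]
    if (!is.na(w) && (origin[v] || mark[v])) mark[w] <- TRUE
  }
  matrix(mark, flow$grid$n_rows, flow$grid$n_cols)
}

#' Benefitting area and relevant population for one NCP
#'
#' Delineates where a solution's critical natural assets deliver their
#' service and who the relevant population is. Benefit areas: cells
#' strictly downstream of selected assets (nitrogen, sediment, flood);
#' within the travel budget of selected assets (access); within the
#' gathering radius (fuelwood); within the protective distance (coastal).
#' Relevant populations: everyone (water quality, access); people within
#' 10 km of floodplains (flood); the coastal strip below 10 m elevation
#' (coastal); the rural poor (fuelwood). Only these six NCP have spatially
#' delineable beneficiaries; the traded material NCP do not.
#'
#' @param ncp one of `"nitrogen"`, `"sediment"`, `"flood"`, `"access"`,
#'   `"fuelwood"`, `"coastal"`.
#' @param solution_mask logical matrix of selected asset cells.
#' @param bundle a `landscape_bundle`.
#' @param flow a `flow_direction` (water-mediated NCP).
#' @param floodplain logical floodplain mask (from [floodplain_mask()]).
#' @param max_minutes access travel budget (default 60).
#' @param gather_radius_km fuelwood gathering radius (default 10).
#' @param protective_distance_cells coastal protective distance.
#' @param elev_cutoff_m coastal relevant-population cutoff (strict `<`).
#' @return list with logical matrices `benefit_mask` and
#'   `relevant_pop_mask`.
#' @export
benefit_mask <- function(ncp, solution_mask, bundle, flow = NULL,
                         floodplain = NULL, max_minutes = 60,
                         gather_radius_km = 10,
                         protective_distance_cells = 2,
                         elev_cutoff_m = 10) {
  ok <- c("nitrogen", "sediment", "flood", "access", "fuelwood", "coastal")
  if (!ncp %in% ok) {
    stop("unsupported error: beneficiaries of '", ncp,
         "' cannot be spatially delineated")
  }
  grid <- bundle$grid
  is_land <- bundle$realm == REALM_CODES[["land"]]
  everyone <- is_land
  if (ncp %in% c("nitrogen", "sediment", "flood")) {
    if (is.null(flow)) stop("flow field required for ", ncp)
    ben <- downstream_of(flow, solution_mask)
    rel <- if (ncp == "flood") {
      if (is.null(floodplain)) stop("floodplain mask required for flood")
      floodplain & is_land
    } else everyone
  } else if (ncp == "access") {
    if (!any(solution_mask)) {
      ben <- matrix(FALSE, grid$n_rows, grid$n_cols)
    } else {
      tf <- travel_time(bundle$friction_min_per_km, solution_mask,
                        grid$cell_size_km)
      ben <- tf$minutes <= max_minutes
    }
    rel <- everyone
  } else if (ncp == "fuelwood") {
    ben <- dilate_mask(solution_mask, gather_radius_km / grid$cell_size_km)
    rel <- bundle$rural_poor > 0
  } else {                       # coastal
    ben <- dilate_mask(solution_mask, protective_distance_cells)
    rel <- is_land & bundle$elevation_m < elev_cutoff_m
  }
  list(benefit_mask = ben, relevant_pop_mask = rel)
}

#' Count beneficiaries of critical natural assets
#'
#' Per NCP, beneficiaries are the population inside the intersection of
#' the benefit area and the relevant-population area. Unique ("local")
#' beneficiaries are counted over the union of those intersections, so a
#' person benefitting from several NCP is counted once; residents are the
#' population living on the selected assets themselves.
#'
#' @param solution_mask logical matrix of selected asset cells.
#' @param bundle a `landscape_bundle`.
#' @param flow a `flow_direction`.
#' @param floodplain logical floodplain mask.
#' @param ncps which delineable NCP to include.
#' @param ... further arguments passed to [benefit_mask()].
#' @return object of class `beneficiary_report`: list with `per_ncp`
#'   (data frame: ncp, beneficiaries, relevant_total), `masks`,
#'   `union_beneficiaries`, `residents`, `population_total`.
#' @export
count_beneficiaries <- function(solution_mask, bundle, flow,
                                floodplain = NULL,
                                ncps = c("nitrogen", "sediment", "flood",
                                         "access", "fuelwood", "coastal"),
                                ...) {
  pop <- bundle$population
  union_area <- matrix(FALSE, bundle$grid$n_rows, bundle$grid$n_cols)
  rows <- list()
  masks <- list()
  for (ncp in ncps) {
    bm <- benefit_mask(ncp, solution_mask, bundle, flow = flow,
                       floodplain = floodplain, ...)
    inter <- bm$benefit_mask & bm$relevant_pop_mask
    union_area <- union_area | inter
    masks[[ncp]] <- bm
    rows[[length(rows) + 1]] <- data.frame(
      ncp = ncp,
      beneficiaries = sum(pop[inter]),
      relevant_total = sum(pop[bm$relevant_pop_mask]))
  }
  per_ncp <- do.call(rbind, rows)
  structure(list(per_ncp = per_ncp, masks = masks,
                 union_beneficiaries = sum(pop[union_area]),
                 residents = sum(pop[solution_mask]),
                 population_total = sum(pop)),
            class = "beneficiary_report")
}

#' @export
print.beneficiary_report <- function(x, ...) {
  cat(sprintf(
    "<beneficiary_report> %.0f unique beneficiaries (%.1f%% of %.0f); %.0f residents\n",
    x$union_beneficiaries,
    100 * x$union_beneficiaries / max(1, x$population_total),
    x$population_total, x$residents))
  print(x$per_ncp, row.names = FALSE)
  invisible(x)
}
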