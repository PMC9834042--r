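#' Construct an NCP layer
#'
#' An NCP layer is a named, non-negative per-pixel contribution surface,
#' zero everywhere off its natural-asset mask, with country/global scale
#' and land/marine realm metadata.
#'
#' @param name layer identifier (see [ncp_layer_names()]).
#' @param values non-negative, finite matrix; forced to zero off-asset.
#' @param scale `"country"` or `"global"`.
#' @param realm `"land"`, `"marine"` or `"both"`.
#' @param units free-text unit description.
#' @param asset an [asset_mask()].
#' @return object of class `ncp_layer`.
#' @export
ncp_layer <- function(name, values, scale = c("country", "global"),
                      realm = c("land", "marine", "both"), units = "",
                      asset = NULL) {
  scale <- match.arg(scale)
  realm <- match.arg(realm)
  values[is.na(values)] <- 0
  if (!is.null(asset)) values[!asset$is_asset] <- 0
  if (any(!is.finite(values))) stop("NCP layer has non-finite values")
  if (any(values < 0)) stop("NCP layer has negative values")
  structure(list(name = name, values = values, scale = scale,
                 realm = realm, units = units,
                 asset = if (is.null(asset)) NULL else asset$is_asset),
            class = "ncp_layer")
}

#' @export
print.ncp_layer <- function(x, ...) {
  cat(sprintf("<ncp_layer> %s [%s/%s] total %.4g (%s)\n", x$name, x$scale,
              x$realm, sum(x$values), x$units))
  invisible(x)
}

#' Nutrient / sediment retention valued by downstream beneficiaries
#'
#' Each cell's exported load travels its D8 flow path; at every
#' natural-asset cell en route (strictly downstream of the source) a
#' class-specific fraction of the *arriving* mass is retained and credited
#' to that cell. The layer is retained mass times the number of people
#' downstream of the retaining cell. Mass is conserved: for every source,
#' load = retained along its path + mass delivered to the outlet.
#'
#' @param loads non-negative load matrix (fertilizer for nitrogen, erosion
#'   for sediment).
#' @param flow a `flow_direction`.
#' @param land_cover land-cover matrix coded by [LC_CLASSES].
#' @param retention_eff named vector, class -> retention efficiency in
#'   `[0, 1]`, applied on asset cells.
#' @param asset an [asset_mask()].
#' @param downstream_pop a `downstream_population`.
#' @param variant `"nitrogen"` or `"sediment"` (layer naming only).
#' @return an `ncp_layer` with attributes `retained` (matrix),
#'   `retained_total` and `delivered_total` for conservation audits.
#' @export
retention_ncp <- function(loads, flow, land_cover, retention_eff, asset,
                          downstream_pop,
                          variant = c("nitrogen", "sediment")) {
  variant <- match.arg(variant)
  if (any(retention_eff < 0 | retention_eff > 1)) {
    stop("parameter error: retention efficiency outside [0, 1]")
  }
  if (any(loads < 0, na.rm = TRUE)) stop("loads must be >= 0")
  eff <- matrix(0, nrow(loads), ncol(loads))
  for (cls in names(retention_eff)) {
    eff[land_cover == LC_CLASSES[[cls]]] <- retention_eff[[cls]]
  }
  eff[!asset$is_asset] <- 0
  ord <- topological_order(flow)
  to <- downstream_index(flow)
  arrive <- numeric(length(loads))
  retained <- numeric(length(loads))
  delivered <- 0
  for (v in ord) {
    retained[v] <- arrive[v] * eff[v]
    out_v <- arrive[v] * (1 - eff[v]) + loads[v]
    w <- to[v]
    if (is.na(w)) delivered <- delivered + out_v
    else arrive[w] <- arrive[w] + out_v
  }
  retained <- matrix(retained, nrow(loads), ncol(loads))
  pd <- downstream_pop$people_downstream
  vals <- retained * ifelse(is.na(pd), 0, pd)
  layer <- ncp_layer(paste0(variant, "_retention"), vals,
                     scale = "country", realm = "land",
                     units = "load retained x persons downstream",
                     asset = asset)
  attr(layer, "retained") <- retained
  attr(layer, "retained_total") <- sum(retained)
  attr(layer, "delivered_total") <- delivered
  layer
}

#' Pollination: habitat sufficiency around cropland, credited to habitat
#'
#' For each cropland cell the habitat sufficiency is the share of
#' natural-asset cells among the valid (non-marine, on-grid) cells within
#' pollinator flight range, excluding the crop cell itself. The realized
#' pollination-dependent production (production x dependency x sufficiency)
#' is mapped from the farm field back to habitat: split equally among the
#' in-range asset cells.
#'
#' @param land_cover,crop_production,dependency co-registered matrices.
#' @param asset an [asset_mask()] of pollinator habitat classes.
#' @param flight_radius_cells pollinator flight range in cells (default 2,
#'   about 4 km on the 2-km grid).
#' @param population_equiv optional linear factor converting production to
#'   equivalent people fed; `NULL` keeps production units.
#' @return an `ncp_layer`.
#' @export
pollination_ncp <- function(land_cover, crop_production, dependency, asset,
                            flight_radius_cells = 2,
                            population_equiv = NULL) {
  if (flight_radius_cells < 1) stop("parameter error: radius must be >= 1")
  nr <- nrow(land_cover); nc <- ncol(land_cover)
  grid <- grid_spec(nr, nc)
  off <- disk_offsets(flight_radius_cells, include_center = FALSE)
  credits <- matrix(0, nr, nc)
  marine <- land_cover == LC_CLASSES[["marine"]]
  crop_cells <- which(land_cover == LC_CLASSES[["cropland"]] &
                        crop_production > 0)
  for (f in crop_cells) {
    r0 <- ((f - 1) %% nr) + 1
    c0 <- ((f - 1) %/% nr) + 1
    rr <- r0 + off$dr
    cc <- c0 + off$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    nb <- rr[ok] + (cc[ok] - 1) * nr
    valid <- nb[!marine[nb]]
    if (!length(valid)) {
      warning("pollination: crop cell ", f, " has no valid neighbourhood")
      next
    }
    hab <- valid[asset$is_asset[valid]]
    if (!length(hab)) next   # sufficiency 0: nothing realized, no credits
    suff <- length(hab) / length(valid)
    realized <- crop_production[f] * dependency[f] * suff
    credits[hab] <- credits[hab] + realized / length(hab)
  }
  units <- "pollination-dependent production (t/yr)"
  if (!is.null(population_equiv)) {
    credits <- credits * population_equiv
    units <- "equivalent people fed"
  }
  ncp_layer("pollination", credits, "country", "land", units, asset)
}

#' Fodder: the smaller of forage supply and livestock demand
#'
#' Per grazing-habitat cell the realized service is `min(supply, demand)`
#' (when consumption exceeds productivity the gap is assumed met with
#' feed). The layer is re-scaled to a 0-1 index by the maximum realized
#' value unless `rescale = FALSE`.
#'
#' @param dry_matter_prod forage supply surface; multiplied by
#'   `supply_scale` before comparison (set `supply_scale = 100 *
#'   cell_area_km2` to convert t/ha/yr to t/cell/yr).
#' @param livestock_demand demand surface (t/yr).
#' @param asset an [asset_mask()] of grazing classes.
#' @param supply_scale multiplier applied to supply.
#' @param rescale divide by the maximum realized value (0-1 index).
#' @return an `ncp_layer`; attribute `realized` holds the unscaled
#'   min(supply, demand) surface.
#' @export
fodder_ncp <- function(dry_matter_prod, livestock_demand, asset,
                       supply_scale = 1, rescale = TRUE) {
  if (any(dry_matter_prod < 0) || any(livestock_demand < 0)) {
    stop("supply and demand must be >= 0")
  }
  realized <- pmin(dry_matter_prod * supply_scale, livestock_demand)
  realized[!asset$is_asset] <- 0
  vals <- realized
  if (rescale) {
    mx <- max(vals)
    if (mx > 0) vals <- vals / mx
    else warning("fodder: all-zero layer, rescale skipped")
  }
  layer <- ncp_layer("fodder", vals, "country", "land",
                     if (rescale) "index 0-1" else "t/yr", asset)
  attr(layer, "realized") <- realized
  layer
}

#' Timber (commercial + domestic) and fuelwood indices
#'
#' Potential sustainable supply per forest cell is aboveground carbon stock
#' times fractional tree cover times the sustainable harvest fraction (the
#' reciprocal of the years needed to rebuild the stock at the annual
#' sequestration rate). Commercial harvest is possible within 6 h travel of
#' a population centre of more than 50,000 people on slopes below 70%;
#' domestic harvest covers the commercially inaccessible cells, capped by
#' per-capita consumption of the population within 10 km; fuelwood is
#' capped by rural-poor demand within 10 km. Commercial and domestic are
#' spatially mutually exclusive by construction. All three layers are
#' re-scaled to 0-1 indices.
#'
#' @param carbon_stock,tree_cover,sequestration_rate co-registered
#'   matrices (tC/ha, fraction, tC/ha/yr).
#' @param travel_minutes matrix of travel minutes to the nearest qualifying
#'   population centre (from [travel_time()]).
#' @param slope_pct slope matrix in percent (>= 0).
#' @param population,rural_poor population matrices (persons/cell).
#' @param asset timber habitat [asset_mask()] (forest).
#' @param asset_fuel fuelwood habitat mask; defaults to `asset`.
#' @param grid a [grid_spec()].
#' @param max_travel_min commercial travel cutoff (<= 360 min).
#' @param max_slope_pct commercial slope cutoff (strictly < 70).
#' @param percap_domestic,percap_fuelwood per-capita consumption (t/yr).
#' @param demand_radius_km consumption radius (10 km).
#' @return list of three `ncp_layer`s: `commercial_timber`,
#'   `domestic_timber`, `fuelwood`. Each carries a `raw` attribute with the
#'   unscaled surface.
#' @export
timber_fuelwood_ncp <- function(carbon_stock, tree_cover,
                                sequestration_rate, travel_minutes,
                                slope_pct, population, rural_poor, asset,
                                asset_fuel = asset, grid,
                                max_travel_min = 360, max_slope_pct = 70,
                                percap_domestic = 0.2,
                                percap_fuelwood = 0.1,
                                demand_radius_km = 10) {
  if (any(slope_pct < 0)) stop("parameter error: negative slope")
  sustain <- ifelse(carbon_stock > 0 & sequestration_rate > 0,
                    sequestration_rate / carbon_stock, 0)
  supply <- carbon_stock * tree_cover * sustain
  supply[supply < 0] <- 0
  accessible <- travel_minutes <= max_travel_min & slope_pct < max_slope_pct
  radius_cells <- demand_radius_km / grid$cell_size_km
  pop_near <- disk_sum(population, radius_cells)
  poor_near <- disk_sum(rural_poor, radius_cells)

  commercial <- supply
  commercial[!accessible] <- 0
  domestic <- pmin(supply, percap_domestic * pop_near)
  domestic[accessible] <- 0
  fuelwood <- pmin(supply, percap_fuelwood * poor_near)

  as_index <- function(raw, name, a) {
    raw[!a$is_asset] <- 0
    mx <- max(raw)
    if (mx > 0) vals <- raw / mx
    else { warning("timber: all-zero ", name, " layer"); vals <- raw }
    layer <- ncp_layer(name, vals, "country", "land", "index 0-1", a)
    attr(layer, "raw") <- raw
    layer
  }
  list(commercial_timber = as_index(commercial, "commercial_timber", asset),
       domestic_timber = as_index(domestic, "domestic_timber", asset),
       fuelwood = as_index(fuelwood, "fuelwood", asset_fuel))
}

#' Flood regulation: green water storage x people downstream
#'
#' The storage index is the unweighted mean of wetland, canopy and soil
#' storage components (each in `[0, 1]`), multiplied by the number of
#' people downstream of the asset cell.
#'
#' @param wetland_storage,canopy_storage,soil_storage matrices in `[0, 1]`.
#' @param downstream_pop a `downstream_population`.
#' @param asset an [asset_mask()].
#' @return an `ncp_layer`.
#' @export
flood_ncp <- function(wetland_storage, canopy_storage, soil_storage,
                      downstream_pop, asset) {
  for (m in list(wetland_storage, canopy_storage, soil_storage)) {
    if (any(m < 0 | m > 1)) {
      stop("parameter error: storage component outside [0, 1]")
    }
  }
  index <- clip01((wetland_storage + canopy_storage + soil_storage) / 3)
  pd <- downstream_pop$people_downstream
  vals <- index * ifelse(is.na(pd), 0, pd)
  ncp_layer("flood_regulation", vals, "country", "land",
            "storage index x persons downstream", asset)
}

#' Nature access: people within travel range of habitat
#'
#' Pass-through of the population-within-1-h field onto the natural-asset
#' mask: each habitat cell is valued by the number of urban and rural
#' people who can reach it within the travel budget.
#'
#' @param pop_within matrix from [population_within()].
#' @param asset an [asset_mask()].
#' @return an `ncp_layer`.
#' @export
access_ncp <- function(pop_within, asset) {
  vals <- pop_within
  vals[is.na(vals)] <- 0
  ncp_layer("nature_access", vals, "country", "land", "persons", asset)
}

#' Fit the riverine fish-catch regression
#'
#' Ordinary least squares of basin fish catch on population density, river
#' discharge and percentage wetland cover (plus intercept), mirroring the
#' literature-compiled basin regression used to spatially disaggregate
#' national catch. Reports R^2 and adjusted R^2 with p = 3 predictors.
#'
#' @param table data frame with columns `catch_t`, `pop_density`,
#'   `discharge`, `wetland_pct` (a `FishBasinTable`).
#' @return list with `coefficients` (intercept + 3 slopes), `r_squared`,
#'   `adj_r_squared`, `n`.
#' @export
fit_fish_regression <- function(table) {
  need <- c("catch_t", "pop_density", "discharge", "wetland_pct")
  if (!all(need %in% names(table))) {
    stop("fish basin table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(table) < 5) stop("fit error: need at least 5 basins")
  if (any(table$catch_t < 0)) stop("fit error: negative catch")
  X <- cbind(1, table$pop_density, table$discharge, table$wetland_pct)
  if (qr(X)$rank < ncol(X)) stop("fit error: singular design")
  fit <- stats::lm(catch_t ~ pop_density + discharge + wetland_pct,
                   data = table)
  n <- nrow(table); p <- 3
  r2 <- summary(fit)$r.squared
  list(coefficients = stats::coef(fit), r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p - 1), n = n)
}

#' Riverine fish catch disaggregated to freshwater habitat
#'
#' Basin catch is predicted from the regression coefficients (floored at
#' zero), rescaled within each region so the basin predictions sum to the
#' region's reported total, and spread uniformly over the basin's
#' freshwater-asset cells as tonnes per km2 per year. Only basins with at
#' least one freshwater-asset cell enter the rescale, so the layer total
#' equals the sum of reported totals over regions with placeable basins.
#'
#' @param coefficients numeric length-4 vector (intercept, pop_density,
#'   discharge, wetland_pct), e.g. from [fit_fish_regression()].
#' @param basins data frame: `basin_id`, `region`, `pop_density`,
#'   `discharge`, `wetland_pct`.
#' @param basin_raster integer matrix of basin ids (NA off-land).
#' @param asset freshwater [asset_mask()].
#' @param national_totals named numeric vector of reported catch (t/yr) per
#'   region.
#' @param grid a [grid_spec()].
#' @param on_unplaceable what to do when a region has reported catch but no
#'   placeable basin: `"error"` (default) or `"skip"` with a warning.
#' @return an `ncp_layer` (t/km2/yr).
#' @export
riverine_fish_ncp <- function(coefficients, basins, basin_raster, asset,
                              national_totals, grid,
                              on_unplaceable = c("error", "skip")) {
  on_unplaceable <- match.arg(on_unplaceable)
  stopifnot(length(coefficients) == 4)
  X <- cbind(1, basins$pop_density, basins$discharge, basins$wetland_pct)
  pred <- pmax(0, as.vector(X %*% coefficients))
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  placeable <- logical(nrow(basins))
  cells_of <- vector("list", nrow(basins))
  for (b in seq_len(nrow(basins))) {
    cells <- which(basin_raster == basins$basin_id[b] & asset$is_asset)
    cells_of[[b]] <- cells
    placeable[b] <- length(cells) > 0
  }
  for (reg in names(national_totals)) {
    rows <- which(basins$region == reg & placeable)
    total <- national_totals[[reg]]
    if (total <= 0) next
    psum <- sum(pred[rows])
    if (!length(rows) || psum == 0) {
      msg <- paste0("disaggregation error: region ", reg,
                    " has reported catch but zero predicted basin total")
      if (on_unplaceable == "error") stop(msg)
      warning(msg, "; region skipped")
      next
    }
    for (b in rows) {
      catch_b <- total * pred[b] / psum
      cells <- cells_of[[b]]
      vals[cells] <- vals[cells] +
        catch_b / (length(cells) * grid$cell_area_km2)
    }
  }
  ncp_layer("riverine_fish", vals, "country", "land", "t/km2/yr", asset)
}

#' Coastal risk reduction credited to protective habitat
#'
#' For each shore segment (cell with positive baseline exposure) the risk
#' reduced by habitat is `exposure_without - exposure_with`; the protected
#' people are the population within the protective distance of the segment
#' living below the elevation cutoff (10 m above mean sea level). The
#' segment value (risk reduced x protected people) is credited equally to
#' the habitat cells, on- or off-shore, within the protective distance.
#'
#' @param exposure_with,exposure_without matrices in `[0, 1]` with
#'   `exposure_with <= exposure_without`; positive only on shore cells.
#' @param protective_distance_cells protective distance (cells).
#' @param population population matrix.
#' @param elevation_m elevation matrix.
#' @param asset protective-habitat [asset_mask()].
#' @param elev_cutoff_m exposed-population elevation cutoff (strict `<`).
#' @return an `ncp_layer` (realm `"both"`: habitat may be off-shore).
#' @export
coastal_ncp <- function(exposure_with, exposure_without,
                        protective_distance_cells = 2, population,
                        elevation_m, asset, elev_cutoff_m = 10) {
  if (any(exposure_without < 0 | exposure_without > 1)) {
    stop("parameter error: exposure outside [0, 1]")
  }
  if (any(exposure_with > exposure_without + 1e-12)) {
    stop("parameter error: exposure_with exceeds exposure_without")
  }
  nr <- nrow(population); nc <- ncol(population)
  off <- disk_offsets(protective_distance_cells)
  vals <- matrix(0, nr, nc)
  exposed <- population * (elevation_m < elev_cutoff_m)
  for (s in which(exposure_without > 0)) {
    r0 <- ((s - 1) %% nr) + 1
    c0 <- ((s - 1) %/% nr) + 1
    rr <- r0 + off$dr; cc <- c0 + off$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    nb <- rr[ok] + (cc[ok] - 1) * nr
    hab <- nb[asset$is_asset[nb]]
    if (!length(hab)) next
    protected_people <- sum(exposed[nb])
    value <- (exposure_without[s] - exposure_with[s]) * protected_people
    vals[hab] <- vals[hab] + value / length(hab)
  }
  ncp_layer("coastal_protection", vals, "country", "both",
            "risk reduced x persons protected", asset)
}

#' Exogenous marine NCP surfaces masked to marine habitat
#'
#' Marine fish catch (t/km2/yr) and reef tourism (expenditure deciles) are
#' exogenous surfaces in this artifact; they are masked to marine asset
#' cells without transformation.
#'
#' @param layer non-negative matrix.
#' @param asset marine [asset_mask()].
#' @param name `"marine_fish"` or `"reef_tourism"`.
#' @return an `ncp_layer`.
#' @export
marine_passthrough <- function(layer, asset,
                               name = c("marine_fish", "reef_tourism")) {
  name <- match.arg(name)
  if (any(layer < 0)) stop("marine layer must be >= 0")
  units <- if (name == "marine_fish") "t/km2/yr" else "expenditure decile"
  ncp_layer(name, layer, "country", "marine", units, asset)
}

#' Vulnerable ecosystem carbon (global NCP)
#'
#' Carbon lost in a typical disturbance event rather than total stock:
#' stock times a class-specific vulnerability fraction times cell area.
#'
#' @param carbon_stock tC/ha matrix.
#' @param vulnerability_frac named vector, class -> fraction in `[0, 1]`.
#'   Every asset class present must be mapped.
#' @param land_cover land-cover matrix.
#' @param asset an [asset_mask()].
#' @param grid a [grid_spec()].
#' @return an `ncp_layer` (tC), scale `"global"`.
#' @export
carbon_ncp <- function(carbon_stock, vulnerability_frac, land_cover, asset,
                       grid) {
  if (any(vulnerability_frac < 0 | vulnerability_frac > 1)) {
    stop("parameter error: vulnerability fraction outside [0, 1]")
  }
  present <- names(LC_CLASSES)[LC_CLASSES %in%
                                 unique(land_cover[asset$is_asset])]
  missing <- setdiff(present, names(vulnerability_frac))
  if (length(missing)) {
    stop("mapping error: no vulnerability fraction for class ",
         paste(missing, collapse = ", "))
  }
  vf <- matrix(0, nrow(land_cover), ncol(land_cover))
  for (cls in names(vulnerability_frac)) {
    vf[land_cover == LC_CLASSES[[cls]]] <- vulnerability_frac[[cls]]
  }
  ha_per_cell <- grid$cell_area_km2 * 100
  ncp_layer("carbon_storage", carbon_stock * vf * ha_per_cell,
            "global", "land", "tC", asset)
}

#' Moisture recycling via a conservative transport kernel (global NCP)
#'
#' Water evapotranspired from vegetated source cells is delivered to
#' receptor cells by a normalized source-to-receptor kernel (rows sum to at
#' most 1; the residual exits the domain). A source cell's NCP is the
#' moisture it delivers onto rain-fed productive land (cropland, rangeland
#' and working forest).
#'
#' @param evapotranspiration mm/yr matrix.
#' @param transport_kernel sparse n x n matrix (`Matrix::dgCMatrix` or
#'   coercible), rows = sources, columns = receptors, column-major cell
#'   indexing.
#' @param rainfed_mask logical matrix of rain-fed productive land.
#' @param vegetation_frac matrix in `[0, 1]`.
#' @param asset an [asset_mask()].
#' @return an `ncp_layer` (mm/yr equivalents), scale `"global"`.
#' @export
moisture_ncp <- function(evapotranspiration, transport_kernel, rainfed_mask,
                         vegetation_frac, asset) {
  rs <- Matrix::rowSums(transport_kernel)
  if (any(rs > 1 + 1e-9)) {
    stop("conservation error: kernel row sums exceed 1")
  }
  if (any(vegetation_frac < 0 | vegetation_frac > 1)) {
    stop("parameter error: vegetation fraction outside [0, 1]")
  }
  reach <- as.vector(transport_kernel %*% as.numeric(rainfed_mask))
  source_flux <- as.vector(evapotranspiration) * as.vector(vegetation_frac)
  vals <- matrix(source_flux * reach, nrow(evapotranspiration),
                 ncol(evapotranspiration))
  ncp_layer("moisture_recycling", vals, "global", "land",
            "ET delivered to rain-fed land", asset)
}
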