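#' Full-run configuration
#'
#' Collects the generator configuration and every fixed constant of the
#' NCP models and the prioritization in one validated object. Defaults are
#' the analysis' stated constants: 1 h access travel (6 h sensitivity
#' variant), 360 min / 50,000-person / <70%-slope commercial timber
#' accessibility, 10 km consumption and floodplain radius, 10 m coastal
#' elevation cutoff, targets from 5% to 100% in 5% steps, and a 90%
#' headline target.
#'
#' @param generator a [generator_config()].
#' @param seed master seed for the run.
#' @param targets_grid accumulation-curve target levels.
#' @param solve_target headline proportional target (0.9).
#' @param solver `"auto"`, `"exact"` or `"greedy"`.
#' @param exact_cap exact-path instance-size cap.
#' @param max_hours access travel budget in hours (1, or 6 for the
#'   sensitivity variant).
#' @param n_species,n_languages overlay counts.
#' @param out_dir output directory (`NULL` = keep results in memory).
#' @param params named list overriding individual model constants; see
#'   `default_ncp_params()` in the source for the full set.
#' @return object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(), seed = 1,
                       targets_grid = seq(0.05, 1, 0.05),
                       solve_target = 0.9, solver = "auto",
                       exact_cap = 20, max_hours = 1,
                       n_species = 30, n_languages = 12,
                       out_dir = NULL, params = list()) {
  stopifnot(inherits(generator, "generator_config"))
  if (any(targets_grid < 0 | targets_grid > 1) ||
      is.unsorted(targets_grid)) {
    stop("targets_grid must be sorted within [0, 1]")
  }
  if (!max_hours %in% c(1, 6)) {
    stop("max_hours must be 1 (default) or 6 (sensitivity)")
  }
  p <- default_ncp_params()
  bad <- setdiff(names(params), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(params)] <- params
  if (any(vapply(p[c("max_travel_min", "centre_min_pop", "max_slope_pct",
                     "gather_radius_km", "elev_cutoff_m",
                     "floodplain_buffer_km")], function(x) x <= 0,
                 logical(1)))) {
    stop("all threshold parameters must be positive")
  }
  structure(list(generator = generator, seed = seed,
                 targets_grid = targets_grid, solve_target = solve_target,
                 solver = solver, exact_cap = exact_cap,
                 max_hours = max_hours, n_species = n_species,
                 n_languages = n_languages, out_dir = out_dir, params = p),
            class = "run_config")
}

default_ncp_params <- function() {
  list(
    max_travel_min = 360,          # commercial timber: within 6 h
    centre_min_pop = 5e4,          # of a >50,000-person centre
    max_slope_pct = 70,            # on slopes strictly below 70%
    gather_radius_km = 10,         # fuelwood / domestic demand radius
    elev_cutoff_m = 10,            # coastal exposed strip (< 10 m a.s.l.)
    flight_radius_cells = 2,       # pollinator flight range (~4 km)
    protective_distance_cells = 2, # coastal protective distance
    floodplain_threshold_cells = 25,
    floodplain_buffer_km = 10,
    percap_domestic = 0.2,         # t/yr per person
    percap_fuelwood = 0.1,
    nitrogen_eff = c(forest = 0.6, wetland = 0.8, grassland = 0.4,
                     sparse = 0.3, inland_water = 0.2),
    sediment_eff = c(forest = 0.7, wetland = 0.6, grassland = 0.5,
                     sparse = 0.35, inland_water = 0.25),
    carbon_vulnerability = c(forest = 0.4, wetland = 0.5,
                             grassland = 0.25, sparse = 0.2),
    fish_coefficients = c(50, 0.8, 12, 3),
    fish_catch_per_km2 = 0.03,     # reported catch density (t/km2/yr)
    moisture_drift_cells = 4,
    moisture_spread_cells = 1.5,
    moisture_efficiency = 0.7,
    asset_classes = NULL           # NULL = default_asset_classes()
  )
}

#' Compute all NCP layers and hydrologic/travel auxiliaries for a bundle
#'
#' Runs the terrain, travel and all 14 NCP models in sequence and returns
#' the 15 layer surfaces (timber splits into commercial and domestic)
#' together with the auxiliary fields downstream stages reuse.
#'
#' @param bundle a `landscape_bundle`.
#' @param config a [run_config()].
#' @return list with `layers` (named list of `ncp_layer`) and `aux`
#'   (flow, downstream population, flow accumulation, floodplain,
#'   centres, travel fields, asset masks).
#' @export
compute_ncp_layers <- function(bundle, config = run_config()) {
  p <- config$params
  grid <- bundle$grid
  lc <- bundle$land_cover
  cls_map <- if (is.null(p$asset_classes)) default_asset_classes()
             else p$asset_classes
  am <- lapply(cls_map, function(cl) asset_mask(lc, cl))
  asset_all <- asset_mask(lc, ASSET_CLASSES)

  flow <- d8_directions(bundle$elevation_m, bundle$realm,
                        grid$cell_size_km)
  dpop <- downstream_population(flow, bundle$population)
  facc <- flow_accumulation(flow)
  floodplain <- floodplain_mask(flow, p$floodplain_threshold_cells,
                                p$floodplain_buffer_km)
  centres <- detect_population_centres(lc, bundle$population,
                                       p$centre_min_pop)
  tt_centres <- if (any(centres)) {
    travel_time(bundle$friction_min_per_km, centres,
                grid$cell_size_km)$minutes
  } else matrix(Inf, grid$n_rows, grid$n_cols)
  pop_within_1h <- population_within(bundle$friction_min_per_km,
                                     bundle$population,
                                     60 * config$max_hours,
                                     cell_size_km = grid$cell_size_km)
  slope <- slope_percent(bundle$elevation_m, grid)
  storage <- storage_components(bundle)
  exposure <- coastal_exposure(bundle, p$protective_distance_cells,
                               seed = config$seed)
  marine <- make_marine_layers(bundle, config$seed)

  layers <- list()
  layers$nitrogen_retention <- retention_ncp(
    bundle$fertilizer_load, flow, lc, p$nitrogen_eff,
    am$nitrogen_retention, dpop, "nitrogen")
  layers$sediment_retention <- retention_ncp(
    bundle$erosion_load, flow, lc, p$sediment_eff,
    am$sediment_retention, dpop, "sediment")
  layers$pollination <- pollination_ncp(
    lc, bundle$crop_production, bundle$pollination_dependency,
    am$pollination, p$flight_radius_cells)
  layers$fodder <- fodder_ncp(
    bundle$dry_matter_prod, bundle$livestock_demand, am$fodder,
    supply_scale = 100 * grid$cell_area_km2)
  tf <- timber_fuelwood_ncp(
    bundle$carbon_stock, bundle$tree_cover, bundle$sequestration_rate,
    tt_centres, slope, bundle$population, bundle$rural_poor,
    am$commercial_timber, am$fuelwood, grid,
    p$max_travel_min, p$max_slope_pct, p$percap_domestic,
    p$percap_fuelwood, p$gather_radius_km)
  layers$commercial_timber <- tf$commercial_timber
  layers$domestic_timber <- tf$domestic_timber
  layers$fuelwood <- tf$fuelwood
  layers$flood_regulation <- flood_ncp(
    storage$wetland, storage$canopy, storage$soil, dpop,
    am$flood_regulation)
  layers$nature_access <- access_ncp(pop_within_1h, am$nature_access)

  basins <- basin_summary(bundle, flow)
  fit <- fit_fish_regression(
    simulate_fish_basins(40, p$fish_coefficients, sigma = 20,
                         seed = config$seed))
  region_areas <- table(bundle$region_id[
    bundle$realm == REALM_CODES[["land"]]]) * grid$cell_area_km2
  totals <- setNames(as.numeric(region_areas) * p$fish_catch_per_km2,
                     names(region_areas))
  # reported catch only for regions that drain an identifiable basin
  totals <- totals[names(totals) %in% as.character(basins$region)]
  layers$riverine_fish <- riverine_fish_ncp(
    fit$coefficients, basins, attr(basins, "basin_raster"),
    am$riverine_fish, totals, grid, on_unplaceable = "skip")
  layers$marine_fish <- marine_passthrough(marine$marine_fish,
                                           am$marine_fish, "marine_fish")
  layers$reef_tourism <- marine_passthrough(marine$reef_tourism,
                                            am$reef_tourism, "reef_tourism")
  layers$coastal_protection <- coastal_ncp(
    exposure$exposure_with, exposure$exposure_without,
    p$protective_distance_cells, bundle$population, bundle$elevation_m,
    am$coastal_protection, p$elev_cutoff_m)
  layers$carbon_storage <- carbon_ncp(
    bundle$carbon_stock, p$carbon_vulnerability, lc, am$carbon_storage,
    grid)
  rainfed <- lc %in% LC_CLASSES[c("cropland", "grassland", "forest")]
  rainfed <- matrix(rainfed, grid$n_rows, grid$n_cols)
  veg_frac <- matrix(0, grid$n_rows, grid$n_cols)
  for (cl in names(LC_CLASSES)) {
    vf <- c(forest = 0.9, grassland = 0.8, wetland = 0.7, sparse = 0.4,
            cropland = 0.6, urban = 0.1, bare = 0.05)[cl]
    if (!is.na(vf)) veg_frac[lc == LC_CLASSES[[cl]]] <- vf
  }
  kernel <- moisture_kernel(grid, p$moisture_drift_cells,
                            p$moisture_spread_cells,
                            p$moisture_efficiency)
  layers$moisture_recycling <- moisture_ncp(
    bundle$evapotranspiration, kernel, rainfed, veg_frac,
    am$moisture_recycling)

  list(layers = layers,
       aux = list(flow = flow, downstream_pop = dpop,
                  flow_accumulation = facc, floodplain = floodplain,
                  centres = centres, travel_to_centres = tt_centres,
                  pop_within = pop_within_1h, slope_pct = slope,
                  asset_masks = am, asset_all = asset_all,
                  basins = basins, exposure = exposure))
}

#' Aggregated NCP display surface
#'
#' Max-normalizes each layer to `[0, 1]` and sums — a display-only product
#' (darker = more aggregated NCP); never used in optimization, where
#' proportional targets make scaling irrelevant.
#'
#' @param layers non-empty list of `ncp_layer`s.
#' @return numeric matrix.
#' @export
aggregate_ncp_display <- function(layers) {
  if (!length(layers)) stop("need at least one layer")
  Reduce(`+`, lapply(layers, function(l) {
    mx <- max(l$values)
    if (mx > 0) l$values / mx else l$values
  }))
}

#' Run the full critical-natural-assets pipeline
#'
#' Generates the landscape and overlays, computes hydrology, travel and
#' all NCP layers, solves the country-scale (local NCP) and global-scale
#' (global NCP) prioritizations at the headline target, derives the
#' accumulation curve, counts beneficiaries and computes overlap
#' statistics. Fully deterministic for a fixed `(config, seed)`. When
#' `config$out_dir` is set, all artifacts are written there (ASCII
#' rasters, GeoJSON regions, CSV tables, YAML config, JSON manifest).
#'
#' @param config a [run_config()].
#' @return object of class `run_result`: list with `bundle`, `overlays`,
#'   `layers`, `aux`, `solutions`, `curve`, `beneficiaries`, `overlap`
#'   and `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  timing <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timing[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  grid_cfg <- config$generator
  bundle <- tick("synthkit", make_landscape(grid_cfg, config$seed))
  overlays <- tick("overlays", make_overlays(
    bundle, config$n_species, config$n_languages, config$seed))
  nl <- tick("ncp_layers", compute_ncp_layers(bundle, config))
  layers <- nl$layers; aux <- nl$aux
  grid <- bundle$grid

  problems_local <- build_problems(
    layers, bundle$region_id, bundle$realm, aux$asset_all, "country",
    c("land", "eez"), config$solve_target, grid)
  problems_global <- build_problems(
    layers, bundle$region_id, bundle$realm, aux$asset_all, "global",
    "land", config$solve_target, grid)
  solve_one <- function(p) switch(config$solver,
    auto = solve_auto(p, exact_cap = config$exact_cap),
    exact = solve_exact(p, exact_cap = max(config$exact_cap, 200)),
    greedy = solve_greedy(p))
  sols_local <- tick("prioritize_local", lapply(problems_local, solve_one))
  sols_global <- tick("prioritize_global",
                      lapply(problems_global, solve_one))

  mask_union <- function(sols, realm = NULL) {
    m <- matrix(FALSE, grid$n_rows, grid$n_cols)
    for (s in sols) {
      if (!is.null(realm) && s$realm != realm) next
      m[s$selected_cells] <- TRUE
    }
    m
  }
  local_land <- mask_union(sols_local, "land")
  local_eez <- mask_union(sols_local, "eez")
  global_land <- mask_union(sols_global)

  curve <- tick("curve", accumulation_curve(
    problems_local, config$targets_grid, config$solver, config$exact_cap))
  benef <- tick("beneficiaries", count_beneficiaries(
    local_land, bundle, aux$flow, aux$floodplain,
    max_minutes = 60 * config$max_hours,
    gather_radius_km = config$params$gather_radius_km,
    protective_distance_cells = config$params$protective_distance_cells,
    elev_cutoff_m = config$params$elev_cutoff_m))

  is_land <- bundle$realm == REALM_CODES[["land"]]
  land_km2 <- sum(is_land) * grid$cell_area_km2
  overlap <- tick("overlaps", list(
    partition = partition_local_global(local_land, global_land, land_km2,
                                       grid$cell_area_km2),
    protected_share_pct = if (any(local_land))
      mask_share(bundle$protected, local_land) else NA_real_,
    species_log_linear = species_coverage(
      overlays, local_land, representation_rule("log_linear")),
    species_min_area = species_coverage(
      overlays, local_land, representation_rule("minimum_area")),
    languages = language_coverage(overlays, local_land)))

  solutions <- list(local = sols_local, global = sols_global,
                    local_land_mask = local_land,
                    local_eez_mask = local_eez,
                    global_land_mask = global_land)
  result <- structure(list(bundle = bundle, overlays = overlays,
                           layers = layers, aux = aux,
                           solutions = solutions, curve = curve,
                           beneficiaries = benef, overlap = overlap),
                      class = "run_result")
  manifest <- build_manifest(config, result, timing)
  result$manifest <- manifest
  if (!is.null(config$out_dir)) write_run_outputs(result, config)
  result
}

build_manifest <- function(config, result, timing) {
  cfg <- config
  cfg$out_dir <- NULL
  layer_hashes <- lapply(result$layers,
                         function(l) digest::digest(l$values))
  list(package = "critnat",
       version = as.character(utils::packageVersion("critnat")),
       seed = config$seed,
       config_hash = digest::digest(cfg),
       grid = unclass(result$bundle$grid),
       layer_hashes = layer_hashes,
       solution_hashes = list(
         local_land = digest::digest(result$solutions$local_land_mask),
         local_eez = digest::digest(result$solutions$local_eez_mask),
         global_land = digest::digest(result$solutions$global_land_mask)),
       curve_hash = digest::digest(result$curve$aggregated),
       union_beneficiaries = result$beneficiaries$union_beneficiaries,
       residents = result$beneficiaries$residents,
       timing = as.list(timing))
}

write_run_outputs <- function(result, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- result$bundle$grid
  rdir <- file.path(dir, "rasters"); dir.create(rdir, showWarnings = FALSE)
  for (nm in c("land_cover", "elevation_m", "population", "region_id",
               "realm")) {
    write_ascii_raster(result$bundle[[nm]],
                       file.path(rdir, paste0(nm, ".asc")), grid)
  }
  ldir <- file.path(dir, "layers"); dir.create(ldir, showWarnings = FALSE)
  for (l in result$layers) write_ncp_layer(l, ldir, grid)
  sdir <- file.path(dir, "solutions"); dir.create(sdir, showWarnings = FALSE)
  for (nm in c("local_land_mask", "local_eez_mask", "global_land_mask")) {
    write_ascii_raster(result$solutions[[nm]] * 1,
                       file.path(sdir, paste0(nm, ".asc")), grid,
                       nodata = 255)
  }
  write.csv(result$curve$per_region,
            file.path(dir, "accumulation_curve_regions.csv"),
            row.names = FALSE)
  write.csv(result$curve$aggregated,
            file.path(dir, "accumulation_curve.csv"), row.names = FALSE)
  write.csv(result$beneficiaries$per_ncp,
            file.path(dir, "beneficiaries.csv"), row.names = FALSE)
  write.csv(result$overlap$partition,
            file.path(dir, "overlap_partition.csv"), row.names = FALSE)
  regions_to_geojson(result$bundle$region_id, grid,
                     file.path(dir, "regions.geojson"))
  write_run_config(config, file.path(dir, "config.yaml"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or a reconstructed `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  obj <- list(generator = unclass(config$generator),
              seed = config$seed, targets_grid = config$targets_grid,
              solve_target = config$solve_target, solver = config$solver,
              exact_cap = config$exact_cap, max_hours = config$max_hours,
              n_species = config$n_species,
              n_languages = config$n_languages,
              params = config$params)
  obj$generator$class_proportions <- as.list(
    config$generator$class_proportions)
  obj$params <- lapply(obj$params, function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  gen <- obj$generator
  gen$class_proportions <- unlist(gen$class_proportions)
  generator <- do.call(generator_config, gen)
  params <- lapply(obj$params, function(x)
    if (is.list(x)) unlist(x) else x)
  run_config(generator = generator, seed = obj$seed,
             targets_grid = obj$targets_grid,
             solve_target = obj$solve_target, solver = obj$solver,
             exact_cap = obj$exact_cap, max_hours = obj$max_hours,
             n_species = obj$n_species, n_languages = obj$n_languages,
             params = params)
}
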