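#' Configuration for the synthetic landscape generator
#'
#' The generator emulates the statistical structure of the real input stack:
#' categorical land cover with a configurable natural/semi-natural share,
#' spatially autocorrelated population concentrated in a few "cities", a DEM
#' with coherent drainage to a ragged coastline, a low-elevation coastal
#' fringe, cropland placed preferentially near settlement, and ancillary
#' surfaces (friction, carbon, productivity, loads) tied to land cover.
#'
#' @param n_rows,n_cols grid dimensions (>= 8).
#' @param cell_size_km cell edge (km); default 2 (the working resolution).
#' @param marine_frac fraction of the grid that is marine (EEZ realm).
#' @param class_proportions named proportions over land classes; must sum
#'   to 1. The default gives 60% natural/semi-natural land.
#' @param n_centres number of population centres.
#' @param centre_pop approximate population of each centre; the default
#'   comfortably exceeds the 50,000-person commercial-timber threshold.
#' @param centre_sigma_cells Gaussian radius of a centre (cells).
#' @param background_pop mean background rural population per land cell.
#' @param rural_poor_frac fraction of non-urban population counted as rural
#'   poor (the fuelwood-relevant population).
#' @param friction_base base friction (min/km); 30 min/km approximates
#'   walking speed.
#' @param n_regions number of planning regions ("countries").
#' @param protected_frac fraction of land under protection.
#' @param smooth_passes autocorrelation strength of the random fields.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_rows = 64, n_cols = 64, cell_size_km = 2,
                             marine_frac = 0.25,
                             class_proportions = c(
                               forest = 0.30, grassland = 0.15,
                               wetland = 0.05, sparse = 0.07,
                               inland_water = 0.03, cropland = 0.20,
                               urban = 0.05, bare = 0.12, ice = 0.03),
                             n_centres = 3, centre_pop = 1.2e5,
                             centre_sigma_cells = 2.5,
                             background_pop = 25,
                             rural_poor_frac = 0.30,
                             friction_base = 30,
                             n_regions = 4, protected_frac = 0.15,
                             smooth_passes = 4) {
  if (n_rows < 8 || n_cols < 8) {
    stop("grid too small: generator requires at least 8x8 cells")
  }
  need <- setdiff(names(LC_CLASSES), "marine")
  if (!setequal(names(class_proportions), need)) {
    stop("configuration error: class_proportions must name exactly: ",
         paste(need, collapse = ", "))
  }
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-6) {
    stop("configuration error: class proportions must be >= 0 and sum to 1")
  }
  if (marine_frac < 0 || marine_frac >= 1) {
    stop("configuration error: marine_frac must be in [0, 1)")
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size_km = cell_size_km, marine_frac = marine_frac,
                 class_proportions = class_proportions[need],
                 n_centres = n_centres, centre_pop = centre_pop,
                 centre_sigma_cells = centre_sigma_cells,
                 background_pop = background_pop,
                 rural_poor_frac = rural_poor_frac,
                 friction_base = friction_base,
                 n_regions = n_regions, protected_frac = protected_frac,
                 smooth_passes = smooth_passes),
            class = "generator_config")
}

# chebyshev-ish BFS distance (in cells) to the nearest TRUE cell
bfs_distance <- function(seed_mask) {
  d <- matrix(Inf, nrow(seed_mask), ncol(seed_mask))
  if (!any(seed_mask)) return(d)
  cur <- seed_mask
  k <- 0
  while (any(cur & !is.finite(d))) {
    d[cur & !is.finite(d)] <- k
    cur <- dilate_mask(cur, 1.5)  # radius 1.5 covers the 8-neighbourhood
    k <- k + 1
  }
  d
}

# squared cell distance from every cell to (r0, c0)
dist2_to <- function(nr, nc, r0, c0) {
  outer((seq_len(nr) - r0)^2, (seq_len(nc) - c0)^2, `+`)
}

#' Generate a seeded synthetic landscape bundle
#'
#' Deterministic for a fixed `(config, seed)`: the master seed fans out to a
#' named RNG sub-stream per raster, so adding a raster does not perturb the
#' others. The emitted elevation is pit-filled, guaranteeing that every land
#' cell has a strictly descending D8 path to the map edge or to a marine
#' cell.
#'
#' @param config a [generator_config()].
#' @param seed integer master seed.
#' @return object of class `landscape_bundle`: a list of co-registered
#'   matrices (see the package vignette for the full field list) plus a
#'   `grid` ([grid_spec()]).
#' @export
make_landscape <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  nr <- config$n_rows; nc <- config$n_cols
  grid <- grid_spec(nr, nc, config$cell_size_km)
  sp <- config$smooth_passes
  rs <- function(name) set.seed(sub_seed(seed, name))

  # --- realm: ragged coastline on the west side -------------------------
  rs("coast")
  score <- matrix(rep((seq_len(nc) - 1) / max(1, nc - 1), each = nr),
                  nr, nc) + 0.8 * smooth_field(nr, nc, sp)
  realm <- matrix(REALM_CODES[["land"]], nr, nc)
  if (config$marine_frac > 0) {
    thr <- stats::quantile(score, config$marine_frac)
    realm[score < thr] <- REALM_CODES[["eez"]]
  }
  is_land <- realm == REALM_CODES[["land"]]
  n_land <- sum(is_land)
  if (n_land == 0) stop("generation error: no land cells")

  # --- elevation: distance-to-coast ramp + ridged noise, pit-filled ----
  rs("elevation")
  d_coast <- bfs_distance(!is_land | edge_mask(nr, nc))
  zel <- smooth_field(nr, nc, sp)
  elev <- (0.5 + stats::plogis(zel)) * 4 * d_coast +
    0.5 * stats::plogis(smooth_field(nr, nc, 1))
  elev[!is_land] <- -10
  elev <- fill_pits(elev, realm)

  # --- population: urban kernels + rural background ---------------------
  rs("population")
  low <- exp(-pmax(elev, 0) / 60)
  low[!is_land] <- 0
  centre_cells <- sample(which(is_land), config$n_centres,
                         prob = low[which(is_land)])
  sig <- config$centre_sigma_cells
  pop <- matrix(0, nr, nc)
  prox <- matrix(0, nr, nc)
  for (cc in centre_cells) {
    r0 <- ((cc - 1) %% nr) + 1
    c0 <- ((cc - 1) %/% nr) + 1
    d2 <- dist2_to(nr, nc, r0, c0)
    pop <- pop + config$centre_pop * exp(-d2 / (2 * sig^2)) / (2 * pi * sig^2)
    prox <- pmax(prox, exp(-d2 / (2 * (3 * sig)^2)))
  }
  pop <- pop + config$background_pop * exp(0.5 * smooth_field(nr, nc, sp))
  pop[!is_land] <- 0

  # --- land cover -------------------------------------------------------
  rs("landcover")
  prp <- config$class_proportions
  lc <- matrix(LC_CLASSES[["marine"]], nr, nc)
  land_idx <- which(is_land)
  counts <- round(prp * n_land)
  counts[length(counts)] <- n_land - sum(counts[-length(counts)])
  # urban on the most populous cells, cropland near settlement, the rest by
  # sorting an elevation-tilted autocorrelated field (water low, ice high)
  remaining <- land_idx
  take <- function(pool, score_vec, k) {
    k <- max(0, min(k, length(pool)))
    pool[order(-score_vec, pool)[seq_len(k)]]
  }
  urb <- take(remaining, pop[remaining], counts[["urban"]])
  lc[urb] <- LC_CLASSES[["urban"]]
  remaining <- setdiff(remaining, urb)
  zc <- smooth_field(nr, nc, sp)
  crop_score <- 0.55 * zc[remaining] + 1.2 * prox[remaining]
  crp <- take(remaining, crop_score, counts[["cropland"]])
  lc[crp] <- LC_CLASSES[["cropland"]]
  remaining <- setdiff(remaining, crp)
  zl <- smooth_field(nr, nc, sp)
  es <- as.vector(scale(elev[remaining]))
  f <- 0.8 * zl[remaining] + 0.9 * es
  ord <- remaining[order(f, remaining)]
  slice_order <- c("inland_water", "wetland", "forest", "grassland",
                   "sparse", "bare", "ice")
  pos <- 0
  for (cls in slice_order) {
    k <- counts[[cls]]
    if (cls == slice_order[length(slice_order)]) k <- length(ord) - pos
    k <- max(0, min(k, length(ord) - pos))
    if (k > 0) lc[ord[pos + seq_len(k)]] <- LC_CLASSES[[cls]]
    pos <- pos + k
  }

  # --- ancillary surfaces ----------------------------------------------
  by_class <- function(tbl, default = 0) {
    out <- matrix(default, nr, nc)
    for (cls in names(tbl)) out[lc == LC_CLASSES[[cls]]] <- tbl[[cls]]
    out
  }
  rs("rural_poor")
  rural_poor <- pop * config$rural_poor_frac
  rural_poor[lc == LC_CLASSES[["urban"]]] <- 0

  rs("friction")
  friction <- config$friction_base * exp(0.35 * smooth_field(nr, nc, sp))
  friction[lc == LC_CLASSES[["urban"]]] <-
    friction[lc == LC_CLASSES[["urban"]]] * 0.5
  friction <- pmin(pmax(friction, 5), 240)

  rs("crops")
  crop_production <- matrix(0, nr, nc)
  on_crop <- lc == LC_CLASSES[["cropland"]]
  crop_production[on_crop] <- 150 * exp(0.5 * smooth_field(nr, nc, sp)[on_crop])
  pollination_dependency <- clip01(stats::plogis(smooth_field(nr, nc, sp)))

  rs("vegetation")
  zv <- smooth_field(nr, nc, sp)
  dry_matter_prod <- pmax2z(by_class(list(
    forest = 8, grassland = 6, wetland = 5, sparse = 3, cropland = 4,
    urban = 0.5, bare = 0.2, ice = 0, inland_water = 0)) * exp(0.3 * zv))
  tree_cover <- clip01(by_class(list(
    forest = 0.8, sparse = 0.3, wetland = 0.4, grassland = 0.1,
    cropland = 0.05, urban = 0.05)) + 0.1 * zv)
  tree_cover[!is_land] <- 0

  rs("livestock")
  livestock_demand <- pmax2z(by_class(list(grassland = 4, sparse = 2,
                                            cropland = 1)) *
                              exp(0.4 * smooth_field(nr, nc, sp)) +
                              0.005 * pop)
  livestock_demand[!is_land] <- 0

  rs("carbon")
  zk <- smooth_field(nr, nc, sp)
  carbon_stock <- pmax2z(by_class(list(
    forest = 120, wetland = 80, grassland = 40, sparse = 25, cropland = 10,
    urban = 5, bare = 2)) * exp(0.25 * zk))
  sequestration_rate <- pmax2z(carbon_stock / 50 * exp(0.2 * zk))

  rs("water")
  evapotranspiration <- pmax2z(600 + 250 * smooth_field(nr, nc, sp))
  evapotranspiration[!is_land] <- 1000

  rs("loads")
  zld <- smooth_field(nr, nc, sp)
  fertilizer_load <- pmax2z(by_class(list(cropland = 100, urban = 40)) *
                             exp(0.4 * zld))
  slope <- slope_percent(elev, grid)
  erosion_load <- pmax2z(by_class(list(cropland = 20, bare = 30,
                                        sparse = 8, grassland = 5,
                                        forest = 2, wetland = 1,
                                        urban = 2, ice = 1)) *
                          (0.2 + slope / 20) * exp(0.3 * zld))

  rs("regions")
  seeds_rc <- sample(land_idx, min(config$n_regions, n_land))
  region_id <- matrix(NA_integer_, nr, nc)
  all_r <- ((seq_len(nr * nc) - 1) %% nr) + 1
  all_c <- ((seq_len(nr * nc) - 1) %/% nr) + 1
  dmin <- matrix(Inf, nr, nc)
  for (i in seq_along(seeds_rc)) {
    r0 <- ((seeds_rc[i] - 1) %% nr) + 1
    c0 <- ((seeds_rc[i] - 1) %/% nr) + 1
    di <- (all_r - r0)^2 + (all_c - c0)^2
    upd <- di < dmin
    region_id[upd] <- i
    dmin[upd] <- di[upd]
  }

  rs("protected")
  zp <- smooth_field(nr, nc, sp)
  protected <- matrix(FALSE, nr, nc)
  if (config$protected_frac > 0) {
    thr <- stats::quantile(zp[is_land], 1 - config$protected_frac)
    protected <- zp >= thr & is_land
  }

  bundle <- structure(list(
    grid = grid, config = config, seed = seed,
    land_cover = lc, elevation_m = elev, population = pop,
    rural_poor = rural_poor, friction_min_per_km = friction,
    crop_production = crop_production,
    pollination_dependency = pollination_dependency,
    dry_matter_prod = dry_matter_prod, tree_cover = tree_cover,
    livestock_demand = livestock_demand, carbon_stock = carbon_stock,
    sequestration_rate = sequestration_rate,
    evapotranspiration = evapotranspiration,
    fertilizer_load = fertilizer_load, erosion_load = erosion_load,
    region_id = region_id, realm = realm, protected = protected),
    class = "landscape_bundle")
  validate_landscape(bundle)
  bundle
}

edge_mask <- function(nr, nc) {
  m <- matrix(FALSE, nr, nc)
  if (nr > 1) { m[1, ] <- TRUE; m[nr, ] <- TRUE }
  if (nc > 1) { m[, 1] <- TRUE; m[, nc] <- TRUE }
  if (nr == 1 && nc == 1) m[] <- TRUE
  m
}

#' Validate a landscape bundle against its type invariants
#'
#' Checks co-registration, the marine/realm equivalence, zero population at
#' sea, crop production confined to cropland, non-negativity of the
#' physical surfaces and positivity of friction.
#'
#' @param bundle a `landscape_bundle`.
#' @return `TRUE` invisibly; stops with an informative message otherwise.
#' @export
validate_landscape <- function(bundle) {
  g <- bundle$grid
  rasters <- c("land_cover", "elevation_m", "population", "rural_poor",
               "friction_min_per_km", "crop_production",
               "pollination_dependency", "dry_matter_prod", "tree_cover",
               "livestock_demand", "carbon_stock", "sequestration_rate",
               "evapotranspiration", "fertilizer_load", "erosion_load",
               "region_id", "realm", "protected")
  for (nm in rasters) {
    m <- bundle[[nm]]
    if (!is.matrix(m) || nrow(m) != g$n_rows || ncol(m) != g$n_cols) {
      stop("raster ", nm, " is not registered to the bundle grid")
    }
  }
  marine <- bundle$land_cover == LC_CLASSES[["marine"]]
  eez <- bundle$realm == REALM_CODES[["eez"]]
  if (!identical(as.vector(marine), as.vector(eez))) {
    stop("invariant violated: marine land-cover class must coincide with ",
         "the eez realm")
  }
  if (any(bundle$population[eez] != 0)) {
    stop("invariant violated: population must be zero on marine cells")
  }
  if (any(bundle$crop_production > 0 &
          bundle$land_cover != LC_CLASSES[["cropland"]])) {
    stop("invariant violated: crop production off cropland")
  }
  if (any(bundle$rural_poor > bundle$population + 1e-9)) {
    stop("invariant violated: rural_poor exceeds population")
  }
  nonneg <- c("population", "rural_poor", "crop_production",
              "dry_matter_prod", "livestock_demand", "carbon_stock",
              "sequestration_rate", "evapotranspiration",
              "fertilizer_load", "erosion_load")
  for (nm in nonneg) {
    if (any(bundle[[nm]] < 0)) stop("invariant violated: ", nm, " < 0")
  }
  if (any(bundle$friction_min_per_km <= 0)) {
    stop("invariant violated: friction must be positive")
  }
  if (any(bundle$pollination_dependency < 0 |
          bundle$pollination_dependency > 1)) {
    stop("invariant violated: pollination dependency outside [0, 1]")
  }
  invisible(TRUE)
}

# largest connected component (8-neighbourhood) of a logical mask
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (all(lab == 0L)) return(mask & FALSE)
  big <- as.integer(names(which.max(table(lab[lab > 0L]))))
  lab == big
}

# integer labelling of connected components (8-neighbourhood)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      for (k in seq_along(D8_DR)) {
        nb <- neighbor_index(cur, k, grid_spec(nr, nc))
        nb <- nb[!is.na(nb)]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        lab[nb] <- nxt
        queue <- c(queue, nb)
      }
      queue <- unique(queue)
    }
  }
  lab
}

# grow one connected blob of `n_target` cells on `allowed`, seeded RNG state
grow_blob <- function(allowed, n_target, grid) {
  idx <- which(allowed)
  if (!length(idx)) stop("generation error: no cells available for blob")
  blob <- matrix(FALSE, grid$n_rows, grid$n_cols)
  start <- idx[sample.int(length(idx), 1)]
  blob[start] <- TRUE
  frontier <- start
  while (sum(blob) < n_target && length(frontier)) {
    pick <- frontier[sample.int(length(frontier), 1)]
    added <- FALSE
    for (k in sample(seq_along(D8_DR))) {
      nb <- neighbor_index(pick, k, grid)
      if (!is.na(nb) && allowed[nb] && !blob[nb]) {
        blob[nb] <- TRUE
        frontier <- c(frontier, nb)
        added <- TRUE
        break
      }
    }
    if (!added) frontier <- setdiff(frontier, pick)
  }
  blob
}

#' Generate species habitat and language overlays
#'
#' Species areas of habitat (AOH) are connected blobs on land whose areas
#' are log-uniform between `range_min_km2` and `range_max_frac` of the land
#' area, emulating realistic range-size spectra spanning several orders of
#' magnitude. Languages are connected blobs with a narrower size range.
#'
#' @param landscape a `landscape_bundle`.
#' @param n_species,n_languages how many overlays to draw (>= 0).
#' @param seed integer seed (fans out per overlay).
#' @param range_min_km2 smallest species range (default 4 km2 = one 2-km
#'   cell).
#' @param range_max_frac largest species range as a fraction of land area.
#' @return object of class `overlay_bundle` with `species` and `languages`
#'   lists; each species entry has `species_id`, `aoh_mask` and
#'   `range_area_km2` (= cell count x cell area).
#' @export
make_overlays <- function(landscape, n_species = 30, n_languages = 12,
                          seed = 1, range_min_km2 = 4,
                          range_max_frac = 0.25) {
  stopifnot(n_species >= 0, n_languages >= 0)
  grid <- landscape$grid
  is_land <- landscape$realm == REALM_CODES[["land"]]
  land_area <- sum(is_land) * grid$cell_area_km2
  if (range_min_km2 > land_area) {
    stop("generation error: requested ranges larger than land area")
  }
  core <- largest_component(is_land)
  max_km2 <- max(range_min_km2, range_max_frac * land_area)
  species <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    set.seed(sub_seed(seed, paste0("species", i)))
    area <- exp(stats::runif(1, log(range_min_km2), log(max_km2)))
    n_target <- max(1L, round(area / grid$cell_area_km2))
    mask <- grow_blob(core, n_target, grid)
    species[[i]] <- list(species_id = sprintf("sp%03d", i),
                         aoh_mask = mask,
                         range_area_km2 = sum(mask) * grid$cell_area_km2)
  }
  languages <- vector("list", n_languages)
  for (i in seq_len(n_languages)) {
    set.seed(sub_seed(seed, paste0("language", i)))
    area <- exp(stats::runif(1, log(5 * grid$cell_area_km2),
                             log(max(10 * grid$cell_area_km2,
                                     0.1 * land_area))))
    n_target <- max(1L, round(area / grid$cell_area_km2))
    languages[[i]] <- list(language_id = sprintf("lang%03d", i),
                           extent_mask = grow_blob(core, n_target, grid))
  }
  structure(list(species = species, languages = languages, grid = grid),
            class = "overlay_bundle")
}
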