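#' Green water storage components from a landscape bundle
#'
#' Deterministic class-based proxies in `[0, 1]` for wetland, canopy and
#' soil storage, the three components of the flood-regulation index.
#'
#' @param bundle a `landscape_bundle`.
#' @return list of three matrices: `wetland`, `canopy`, `soil`.
#' @export
storage_components <- function(bundle) {
  lc <- bundle$land_cover
  cls <- function(tbl) {
    out <- matrix(0, nrow(lc), ncol(lc))
    for (nm in names(tbl)) out[lc == LC_CLASSES[[nm]]] <- tbl[[nm]]
    out
  }
  wetland <- cls(list(wetland = 0.9, inland_water = 0.6, forest = 0.2,
                      grassland = 0.1))
  canopy <- clip01(0.9 * bundle$tree_cover)
  slope <- slope_percent(bundle$elevation_m, bundle$grid)
  soil <- clip01(0.2 + 0.5 * clip01(1 - slope / 100))
  soil[bundle$realm == REALM_CODES[["eez"]]] <- 0
  list(wetland = wetland, canopy = canopy, soil = soil)
}

#' Synthetic coastal exposure with and without protective habitat
#'
#' Shore cells (land cells touching marine water) get a baseline exposure
#' index; habitat within the protective distance attenuates it linearly
#' with the habitat share of the neighbourhood. Where no habitat lies
#' within reach, `with == without` (no risk reduced).
#'
#' @param bundle a `landscape_bundle`.
#' @param protective_distance_cells protective distance (cells).
#' @param attenuation maximum fractional risk reduction at full habitat
#'   cover.
#' @param seed RNG seed for the baseline exposure field.
#' @return list with matrices `exposure_with`, `exposure_without` and the
#'   logical `shore` mask.
#' @export
coastal_exposure <- function(bundle, protective_distance_cells = 2,
                             attenuation = 0.7, seed = 1) {
  lc <- bundle$land_cover
  is_land <- bundle$realm == REALM_CODES[["land"]]
  marine <- !is_land
  shore <- is_land & dilate_mask(marine, 1.5)
  set.seed(sub_seed(seed, "coastal_exposure"))
  z <- smooth_field(nrow(lc), ncol(lc), 3)
  without <- matrix(0, nrow(lc), ncol(lc))
  without[shore] <- clip01(0.55 + 0.25 * z[shore])
  hab <- asset_mask(lc, default_asset_classes()$coastal_protection)$is_asset
  n_hab <- disk_sum(hab * 1, protective_distance_cells)
  n_all <- disk_sum(matrix(1, nrow(lc), ncol(lc)),
                    protective_distance_cells)
  frac <- ifelse(n_all > 0, n_hab / n_all, 0)
  with <- without * (1 - attenuation * clip01(frac))
  with[n_hab == 0] <- without[n_hab == 0]   # no habitat, nothing reduced
  list(exposure_with = with, exposure_without = without, shore = shore)
}

#' Conservative atmospheric moisture transport kernel
#'
#' Sparse source-to-receptor weights emulating prevailing-wind moisture
#' transport: each source's evapotranspired moisture is spread over a
#' Gaussian plume displaced `drift_cells` eastward, scaled so each row
#' sums to `efficiency` (< 1; the rest leaves the domain, and plumes
#' truncated by the map edge lose more).
#'
#' @param grid a [grid_spec()].
#' @param drift_cells eastward displacement of the plume centre.
#' @param spread_cells Gaussian spread of the plume.
#' @param efficiency in-domain recycling fraction per row (<= 1).
#' @return a sparse `Matrix::dgCMatrix` (n cells x n cells).
#' @export
moisture_kernel <- function(grid, drift_cells = 4, spread_cells = 1.5,
                            efficiency = 0.7) {
  stopifnot(efficiency > 0, efficiency <= 1)
  nr <- grid$n_rows; nc <- grid$n_cols
  w <- ceiling(3 * spread_cells)
  offs <- expand.grid(dr = -w:w, dc = (drift_cells - w):(drift_cells + w))
  wt <- exp(-((offs$dr)^2 + (offs$dc - drift_cells)^2) /
              (2 * spread_cells^2))
  wt <- wt / sum(wt) * efficiency
  n <- nr * nc
  cell_r <- ((seq_len(n) - 1) %% nr) + 1
  cell_c <- ((seq_len(n) - 1) %/% nr) + 1
  ii <- jj <- integer(0); xx <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    rr <- cell_r + offs$dr[k]
    cc <- cell_c + offs$dc[k]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    ii <- c(ii, which(ok))
    jj <- c(jj, rr[ok] + (cc[ok] - 1) * nr)
    xx <- c(xx, rep(wt[k], sum(ok)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Synthetic marine fish-catch and reef-tourism surfaces
#'
#' Catch is a positive autocorrelated surface on EEZ cells (t/km2/yr);
#' reef tourism assigns expenditure deciles 1-10 to near-shore marine
#' cells (reef proxy) and 0 elsewhere.
#'
#' @param bundle a `landscape_bundle`.
#' @param seed RNG seed.
#' @return list with matrices `marine_fish` and `reef_tourism`.
#' @export
make_marine_layers <- function(bundle, seed = 1) {
  nr <- bundle$grid$n_rows; nc <- bundle$grid$n_cols
  eez <- bundle$realm == REALM_CODES[["eez"]]
  set.seed(sub_seed(seed, "marine_fish"))
  catch <- matrix(0, nr, nc)
  catch[eez] <- 3 * exp(0.5 * smooth_field(nr, nc, 3)[eez])
  set.seed(sub_seed(seed, "reef_tourism"))
  reef_zone <- eez & dilate_mask(!eez, 2)
  tourism <- matrix(0, nr, nc)
  if (any(reef_zone)) {
    z <- smooth_field(nr, nc, 3)[reef_zone]
    tourism[reef_zone] <- as.numeric(cut(z, breaks = stats::quantile(
      z, probs = seq(0, 1, 0.1)), include.lowest = TRUE, labels = FALSE))
  }
  list(marine_fish = catch, reef_tourism = tourism)
}

#' Summarise river basins for the fish-catch regression
#'
#' Basins are the D8 catchments of each outlet (small ones below
#' `min_cells` dropped). Predictors per basin: population density
#' (persons/km2), a discharge proxy (maximum flow accumulation weighted by
#' evapotranspiration, scaled), and percentage wetland cover.
#'
#' @param bundle a `landscape_bundle`.
#' @param flow a `flow_direction` for the bundle.
#' @param min_cells smallest basin retained.
#' @return data frame: `basin_id`, `region`, `area_km2`, `pop_density`,
#'   `discharge`, `wetland_pct`; plus the basin-label matrix as attribute
#'   `basin_raster`.
#' @export
basin_summary <- function(bundle, flow, min_cells = 5) {
  lab <- basin_labels(flow)
  acc <- flow_accumulation(flow, bundle$evapotranspiration)
  ids <- sort(unique(lab[!is.na(lab)]))
  rows <- list()
  for (id in ids) {
    cells <- which(lab == id)
    if (length(cells) < min_cells) {
      lab[cells] <- NA_integer_
      next
    }
    area <- length(cells) * bundle$grid$cell_area_km2
    reg <- bundle$region_id[cells]
    reg <- if (all(is.na(reg))) NA_integer_ else
      as.integer(names(which.max(table(reg))))
    rows[[length(rows) + 1]] <- data.frame(
      basin_id = id,
      region = reg,
      area_km2 = area,
      pop_density = sum(bundle$population[cells]) / area,
      discharge = max(acc[cells]) / 1e4,
      wetland_pct = 100 * mean(bundle$land_cover[cells] %in%
                                 LC_CLASSES[c("wetland", "inland_water")]))
  }
  out <- do.call(rbind, rows)
  attr(out, "basin_raster") <- lab
  out
}

#' Simulate a fish-basin table from known coefficients
#'
#' Draws predictors and generates catch from a linear model with Gaussian
#' noise; the oracle fixture for regression-recovery tests.
#'
#' @param n number of basins.
#' @param coefficients length-4 vector (intercept, pop_density, discharge,
#'   wetland_pct).
#' @param sigma noise standard deviation (0 = noiseless).
#' @param seed RNG seed.
#' @return a `FishBasinTable` data frame.
#' @export
simulate_fish_basins <- function(n = 40,
                                 coefficients = c(50, 0.8, 12, 3),
                                 sigma = 20, seed = 1) {
  set.seed(sub_seed(seed, "fish_basins"))
  tbl <- data.frame(
    basin_id = seq_len(n),
    pop_density = stats::runif(n, 1, 500),
    discharge = stats::runif(n, 0.1, 50),
    wetland_pct = stats::runif(n, 0, 40))
  mu <- coefficients[1] + coefficients[2] * tbl$pop_density +
    coefficients[3] * tbl$discharge + coefficients[4] * tbl$wetland_pct
  tbl$catch_t <- pmax(0, mu + stats::rnorm(n, 0, sigma))
  tbl
}
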