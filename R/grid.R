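#' Grid specification for a landscape bundle
#'
#' All rasters in one bundle are plain R matrices sharing a single
#' `grid_spec`. Cells are addressed by their column-major index
#' (`cell = row + (col - 1) * n_rows`), matching base-R matrix indexing.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param cell_size_km edge length of a (square, equal-area) cell in km;
#'   default 2, the working resolution of the analysis.
#' @return an object of class `grid_spec` with fields `n_rows`, `n_cols`,
#'   `cell_size_km` and `cell_area_km2`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_km = 2) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size_km > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size_km = cell_size_km,
                 cell_area_km2 = cell_size_km^2),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.3g km cells (%.3g km2)\n",
              x$n_rows, x$n_cols, x$cell_size_km, x$cell_area_km2))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

# D8 neighbour order is fixed package-wide: 1=E 2=SE 3=S 4=SW 5=W 6=NW 7=N
# 8=NE. Ties in steepest descent are broken by this order (E before N).
D8_CODES <- c("E", "SE", "S", "SW", "W", "NW", "N", "NE")
D8_DR <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
D8_DIST <- ifelse(D8_DR != 0L & D8_DC != 0L, sqrt(2), 1)

# Neighbour cell index in direction k, NA off-grid. Vectorised over cells.
neighbor_index <- function(cells, k, grid) {
  nr <- grid$n_rows
  r <- ((cells - 1L) %% nr) + 1L
  c <- ((cells - 1L) %/% nr) + 1L
  rr <- r + D8_DR[k]
  cc <- c + D8_DC[k]
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= grid$n_cols
  out <- rep(NA_integer_, length(cells))
  out[ok] <- rr[ok] + (cc[ok] - 1L) * nr
  out
}

# Shift a matrix by (dr, dc), padding by replicating the nearest edge.
shift_pad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Spatially autocorrelated standard-normal-ish field: white noise smoothed
# by repeated 3x3 box filtering, then re-standardised.
smooth_field <- function(n_rows, n_cols, passes = 4) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  for (p in seq_len(passes)) {
    acc <- z
    for (k in seq_along(D8_DR)) acc <- acc + shift_pad(z, D8_DR[k], D8_DC[k])
    z <- acc / 9
  }
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- (z - mean(z)) / s
  z
}

# Relative (dr, dc) offsets of the cells within Euclidean distance
# `radius_cells` of a focal cell, optionally excluding the focal cell.
disk_offsets <- function(radius_cells, include_center = TRUE) {
  r <- ceiling(radius_cells)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 <= radius_cells^2 + 1e-9
  if (!include_center) keep <- keep & !(g$dr == 0 & g$dc == 0)
  g[keep, , drop = FALSE]
}

# Binary dilation of a logical matrix by a Euclidean disk of radius (cells).
dilate_mask <- function(mask, radius_cells) {
  if (radius_cells <= 0) return(mask)
  off <- disk_offsets(radius_cells)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_pad_logical(mask, off$dr[i], off$dc[i])
  }
  out
}

# logical shift with FALSE padding (dilation must not bleed from edges)
shift_pad_logical <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  r0 <- max(1L, 1L + dr); r1 <- min(nr, nr + dr)
  c0 <- max(1L, 1L + dc); c1 <- min(nc, nc + dc)
  if (r0 <= r1 && c0 <= c1) {
    rs <- r0:r1; cs <- c0:c1
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  }
  out
}

# Sum of `values` over the disk neighbourhood of every cell (edge-truncated).
disk_sum <- function(values, radius_cells, include_center = TRUE) {
  off <- disk_offsets(radius_cells, include_center)
  out <- matrix(0, nrow(values), ncol(values))
  for (i in seq_len(nrow(off))) {
    out <- out + shift_pad_numeric(values, off$dr[i], off$dc[i])
  }
  out
}

shift_pad_numeric <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  r0 <- max(1L, 1L + dr); r1 <- min(nr, nr + dr)
  c0 <- max(1L, 1L + dc); c1 <- min(nc, nc + dc)
  if (r0 <= r1 && c0 <= c1) {
    rs <- r0:r1; cs <- c0:c1
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  }
  out
}

#' Slope in percent from an elevation raster
#'
#' Maximum D8 rise/run to any neighbour, expressed in percent
#' (100 * drop / horizontal distance).
#'
#' @param elevation_m elevation matrix (m).
#' @param grid a [grid_spec()].
#' @return matrix of slope percentages (>= 0).
#' @export
slope_percent <- function(elevation_m, grid) {
  cell_m <- grid$cell_size_km * 1000
  best <- matrix(0, nrow(elevation_m), ncol(elevation_m))
  for (k in seq_along(D8_DR)) {
    nb <- shift_pad(elevation_m, -D8_DR[k], -D8_DC[k])
    g <- abs(elevation_m - nb) / (cell_m * D8_DIST[k])
    best <- pmax(best, g)
  }
  best * 100
}

# Deterministic sub-stream seed: one master integer fans out to named
# streams so adding a raster never perturbs the others. Kept below 2^31.
sub_seed <- function(seed, name) {
  h <- as.numeric(seed) %% 2147480009   # double arithmetic: 131*2^31 < 2^53
  for (code in utf8ToInt(name)) {
    h <- (h * 131 + code) %% 2147480009
  }
  as.integer(h) + 1L
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# elementwise max(x, 0) preserving matrix shape (pmax(0, m) drops dim)
pmax2z <- function(x) { x[x < 0] <- 0; x }
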