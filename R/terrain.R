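#' Depression filling with an epsilon gradient
#'
#' Priority-flood filling: after filling, every land cell has a strictly
#' descending D8 path to an outlet (a map-edge cell or a cell adjacent to
#' marine water). Flats are resolved by the epsilon increments the flood
#' applies, so routing is deterministic. Already-draining surfaces are
#' returned unchanged; the filled surface is pointwise >= the input.
#'
#' @param elevation elevation matrix (m); finite on land.
#' @param realm realm matrix (1 = land, 2 = eez) or a logical land mask.
#' @param eps epsilon increment applied to raised cells (m).
#' @return filled elevation matrix.
#' @export
fill_pits <- function(elevation, realm, eps = 1e-6) {
  land <- realm_to_land(realm, elevation)
  if (!any(land)) stop("empty-domain error: no land cells to fill")
  if (any(!is.finite(elevation[land]))) {
    stop("non-finite elevation on land")
  }
  cpp_fill_pits(elevation, land, eps)
}

realm_to_land <- function(realm, template) {
  if (is.logical(realm)) {
    matrix(realm, nrow(template), ncol(template))
  } else {
    realm == REALM_CODES[["land"]]
  }
}

#' D8 flow directions from a pit-filled DEM
#'
#' Each land cell points to the steepest-descent land neighbour (gradient =
#' drop / distance, diagonal distance = cell size x sqrt(2)). Cells with no
#' lower land neighbour are outlets when adjacent to marine water or on the
#' map edge. Ties are broken by the fixed code order E, SE, S, SW, W, NW,
#' N, NE.
#'
#' @param elevation pit-filled elevation matrix.
#' @param realm realm matrix or logical land mask.
#' @param cell_size_km cell edge length (km); only affects operations that
#'   need physical distances downstream of the direction field.
#' @return object of class `flow_direction`: list with `grid`, `direction`
#'   (integer matrix: 1..8 per [D8_CODES], 0 = outlet, NA = marine).
#' @export
d8_directions <- function(elevation, realm, cell_size_km = 2) {
  land <- realm_to_land(realm, elevation)
  nr <- nrow(elevation); nc <- ncol(elevation)
  grid <- grid_spec(nr, nc, cell_size_km)
  dir <- matrix(NA_integer_, nr, nc)
  best_grad <- matrix(0, nr, nc)
  adj_marine <- matrix(FALSE, nr, nc)
  for (k in seq_along(D8_DR)) {
    nb_elev <- shift_pad(elevation, -D8_DR[k], -D8_DC[k])
    nb_land <- shift_pad_logical(land, -D8_DR[k], -D8_DC[k])
    # off-grid neighbours replicate the edge; exclude them explicitly
    on_grid <- shift_pad_logical(matrix(TRUE, nr, nc), -D8_DR[k], -D8_DC[k])
    adj_marine <- adj_marine | (on_grid & !nb_land)
    grad <- (elevation - nb_elev) / D8_DIST[k]
    cand <- land & on_grid & nb_land & grad > best_grad
    dir[cand] <- k
    best_grad[cand] <- grad[cand]
  }
  none <- land & is.na(dir)
  on_edge <- edge_mask(nr, nc)
  outlet <- none & (adj_marine | on_edge)
  dir[outlet] <- 0L
  if (any(land & is.na(dir))) {
    stop("routing error: unresolved flat or pit after filling")
  }
  structure(list(grid = grid, direction = dir, land = land),
            class = "flow_direction")
}

# downstream cell index for every cell (NA for outlets/marine)
downstream_index <- function(flow) {
  dir <- flow$direction
  n <- length(dir)
  to <- rep(NA_integer_, n)
  for (k in seq_along(D8_DR)) {
    idx <- which(dir == k)
    if (length(idx)) to[idx] <- neighbor_index(idx, k, flow$grid)
  }
  to
}

# topological order of land cells (upstream before downstream); errors on
# cycles. Returns integer vector of cell indices.
topological_order <- function(flow) {
  to <- downstream_index(flow)
  cells <- which(!is.na(flow$direction))
  indeg <- integer(length(to))
  tt <- to[cells]
  tt <- tt[!is.na(tt)]
  tab <- tabulate(tt, nbins = length(to))
  indeg[cells] <- tab[cells]
  queue <- cells[indeg[cells] == 0L]
  out <- integer(length(cells))
  pos <- 0L
  head_i <- 1L
  queue <- c(queue, rep(NA_integer_, length(cells)))
  tail_i <- sum(!is.na(queue))
  while (head_i <= tail_i) {
    v <- queue[head_i]; head_i <- head_i + 1L
    pos <- pos + 1L
    out[pos] <- v
    w <- to[v]
    if (!is.na(w)) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) {
        tail_i <- tail_i + 1L
        queue[tail_i] <- w
      }
    }
  }
  if (pos != length(cells)) stop("routing error: cycle detected in flow")
  out[seq_len(pos)]
}

#' Population strictly downstream of every cell
#'
#' `people_downstream(x)` is the total population over all cells strictly
#' downstream of `x` along the D8 path; the cell's own residents are
#' excluded (they live *on*, not *downstream of*, the pixel). Set
#' `include_self = TRUE` to include them instead.
#'
#' @param flow a `flow_direction`.
#' @param population population matrix (persons/cell).
#' @param include_self include the cell's own population in its count.
#' @return object of class `downstream_population`: list with `grid` and
#'   `people_downstream` matrix (0 on outlets, NA on marine).
#' @export
downstream_population <- function(flow, population, include_self = FALSE) {
  ord <- topological_order(flow)
  to <- downstream_index(flow)
  pd <- matrix(NA_real_, flow$grid$n_rows, flow$grid$n_cols)
  pd[!is.na(flow$direction)] <- 0
  for (v in rev(ord)) {          # downstream cells first
    w <- to[v]
    if (!is.na(w)) pd[v] <- pd[w] + population[w]
  }
  if (include_self) pd <- pd + ifelse(is.na(pd), NA, population)
  structure(list(grid = flow$grid, people_downstream = pd),
            class = "downstream_population")
}

#' D8 flow accumulation (contributing cells, including self)
#'
#' @param flow a `flow_direction`.
#' @param weights optional weight matrix (defaults to 1 per cell).
#' @return matrix of accumulated weights (NA on marine).
#' @export
flow_accumulation <- function(flow, weights = NULL) {
  if (is.null(weights)) {
    weights <- matrix(1, flow$grid$n_rows, flow$grid$n_cols)
  }
  ord <- topological_order(flow)
  to <- downstream_index(flow)
  acc <- matrix(NA_real_, flow$grid$n_rows, flow$grid$n_cols)
  acc[!is.na(flow$direction)] <- weights[!is.na(flow$direction)]
  for (v in ord) {               # upstream cells first
    w <- to[v]
    if (!is.na(w)) acc[w] <- acc[w] + acc[v]
  }
  acc
}

#' Floodplain proxy: high-accumulation cells plus a buffer
#'
#' Marks cells whose flow accumulation (cell count) reaches
#' `accum_threshold_cells`, then dilates the marked set by `buffer_km`
#' (default 10 km, the radius within which flood-relevant populations
#' live). The floodplain itself is a proxy; the real layer is external.
#'
#' @param flow a `flow_direction`.
#' @param accum_threshold_cells accumulation threshold (default 25 cells).
#' @param buffer_km dilation radius in km.
#' @return logical matrix.
#' @export
floodplain_mask <- function(flow, accum_threshold_cells = 25,
                            buffer_km = 10) {
  if (accum_threshold_cells < 0) stop("parameter error: negative threshold")
  if (buffer_km < 0) stop("parameter error: negative buffer")
  acc <- flow_accumulation(flow)
  core <- !is.na(acc) & acc >= accum_threshold_cells
  dilate_mask(core, buffer_km / flow$grid$cell_size_km)
}

# label every land cell with the index of its terminal outlet cell
basin_labels <- function(flow) {
  ord <- topological_order(flow)
  to <- downstream_index(flow)
  lab <- rep(NA_integer_, length(flow$direction))
  for (v in rev(ord)) {
    w <- to[v]
    lab[v] <- if (is.na(w)) v else lab[w]
  }
  matrix(lab, flow$grid$n_rows, flow$grid$n_cols)
}
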