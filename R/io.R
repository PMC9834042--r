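#' Write a raster matrix as an ESRI ASCII grid
#'
#' Plain-text, GDAL-readable single-band raster registered to a synthetic
#' equal-area grid with the bundle's cell size (metres). Row 1 of the
#' matrix is the northernmost row. `NA` is written as the nodata value.
#'
#' @param values numeric or logical matrix.
#' @param path output `.asc` path.
#' @param grid a [grid_spec()].
#' @param nodata nodata sentinel (default -9999; use 255 for categorical
#'   uint8-style layers).
#' @return `path`, invisibly.
#' @export
write_ascii_raster <- function(values, path, grid, nodata = -9999) {
  m <- values
  mode(m) <- "numeric"
  m[is.na(m) | is.infinite(m)] <- nodata
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           "xllcorner 0", "yllcorner 0",
           sprintf("cellsize %.10g", grid$cell_size_km * 1000),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1, function(r) paste(sprintf("%.10g", r),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_raster()]
#'
#' @param path `.asc` path.
#' @param na_nodata convert nodata back to `NA`.
#' @return list with `values` matrix, `grid` and `nodata`.
#' @export
read_ascii_raster <- function(path, na_nodata = TRUE) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], " +")
  kv <- setNames(vapply(hdr, `[`, "", 2), tolower(vapply(hdr, `[`, "", 1)))
  nc <- as.integer(kv[["ncols"]]); nr <- as.integer(kv[["nrows"]])
  nodata <- as.numeric(kv[["nodata_value"]])
  vals <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"),
                      quiet = TRUE), nrow = nr, ncol = nc, byrow = TRUE)
  if (na_nodata) vals[vals == nodata] <- NA
  list(values = vals,
       grid = grid_spec(nr, nc, as.numeric(kv[["cellsize"]]) / 1000),
       nodata = nodata)
}

#' Write an NCP layer with its JSON metadata sidecar
#'
#' @param layer an `ncp_layer`.
#' @param dir output directory.
#' @param grid a [grid_spec()].
#' @return the raster path, invisibly.
#' @export
write_ncp_layer <- function(layer, dir, grid) {
  asc <- file.path(dir, paste0(layer$name, ".asc"))
  write_ascii_raster(layer$values, asc, grid)
  meta <- list(name = layer$name, scale = layer$scale, realm = layer$realm,
               units = layer$units, total = sum(layer$values),
               provenance_sha = digest::digest(layer$values))
  jsonlite::write_json(meta, file.path(dir, paste0(layer$name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(asc)
}

#' Write region footprints as GeoJSON
#'
#' Each region becomes a MultiPolygon of row-run rectangles in the
#' synthetic equal-area coordinate system (metres, origin at the
#' south-west corner).
#'
#' @param region_id integer region matrix.
#' @param grid a [grid_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
regions_to_geojson <- function(region_id, grid, path) {
  cs <- grid$cell_size_km * 1000
  nr <- grid$n_rows
  features <- list()
  for (id in sort(unique(region_id[!is.na(region_id)]))) {
    polys <- list()
    for (r in seq_len(nr)) {
      row <- which(!is.na(region_id[r, ]) & region_id[r, ] == id)
      if (!length(row)) next
      breaks <- c(0, which(diff(row) != 1), length(row))
      for (b in seq_len(length(breaks) - 1)) {
        run <- row[(breaks[b] + 1):breaks[b + 1]]
        x0 <- (min(run) - 1) * cs; x1 <- max(run) * cs
        y0 <- (nr - r) * cs; y1 <- (nr - r + 1) * cs
        polys[[length(polys) + 1]] <- list(list(
          c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
      }
    }
    features[[length(features) + 1]] <- list(
      type = "Feature",
      properties = list(region_id = id),
      geometry = list(type = "MultiPolygon", coordinates = polys))
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
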