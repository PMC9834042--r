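#' Land-cover classes and natural-asset masks
#'
#' The synthetic land-cover legend has ten classes. Natural assets are the
#' natural and semi-natural classes (including semi-natural rangelands and
#' production forests) plus inland and marine waters; cropland, urban, bare
#' and permanent ice are never assets.
#'
#' @name landcover
NULL

#' @rdname landcover
#' @format `LC_CLASSES` is a named integer vector mapping class name to the
#'   code stored in the `land_cover` raster.
#' @export
LC_CLASSES <- c(forest = 1L, grassland = 2L, wetland = 3L, sparse = 4L,
                cropland = 5L, urban = 6L, bare = 7L, ice = 8L,
                inland_water = 9L, marine = 10L)

#' @rdname landcover
#' @export
NATURAL_CLASSES <- c("forest", "grassland", "wetland", "sparse",
                     "inland_water")

#' @rdname landcover
#' @export
ASSET_CLASSES <- c(NATURAL_CLASSES, "marine")

REALM_CODES <- c(land = 1L, eez = 2L)

#' Build a per-NCP natural-asset mask
#'
#' @param land_cover integer land-cover matrix coded by [LC_CLASSES].
#' @param classes character vector of asset classes for this NCP. Must be a
#'   subset of [ASSET_CLASSES]; cropland, urban, bare and ice are rejected.
#' @return object of class `asset_mask`: list with `is_asset` (logical
#'   matrix) and `classes`.
#' @export
asset_mask <- function(land_cover, classes = ASSET_CLASSES) {
  bad <- setdiff(classes, ASSET_CLASSES)
  if (length(bad)) {
    stop("non-asset classes requested in asset mask: ",
         paste(bad, collapse = ", "))
  }
  codes <- LC_CLASSES[classes]
  structure(list(is_asset = matrix(land_cover %in% codes,
                                   nrow(land_cover), ncol(land_cover)),
                 classes = classes),
            class = "asset_mask")
}

# default asset-class mapping per NCP layer (configurable via run_config)
default_asset_classes <- function() {
  list(
    nitrogen_retention = NATURAL_CLASSES,
    sediment_retention = NATURAL_CLASSES,
    pollination        = setdiff(NATURAL_CLASSES, "inland_water"),
    fodder             = c("grassland", "sparse"),
    commercial_timber  = "forest",
    domestic_timber    = "forest",
    fuelwood           = c("forest", "sparse"),
    flood_regulation   = NATURAL_CLASSES,
    nature_access      = NATURAL_CLASSES,
    riverine_fish      = c("inland_water", "wetland"),
    marine_fish        = "marine",
    reef_tourism       = "marine",
    coastal_protection = c("forest", "wetland", "marine"),
    carbon_storage     = setdiff(NATURAL_CLASSES, "inland_water"),
    moisture_recycling = setdiff(NATURAL_CLASSES, "inland_water")
  )
}

#' Canonical NCP layer names
#'
#' 15 layer surfaces represent the 14 NCP: timber contributes two spatially
#' mutually exclusive layers (commercial and domestic). Twelve NCP (13
#' layers) are "local" (optimized per country); carbon storage and moisture
#' recycling are "global".
#' @return list with `local` and `global` character vectors.
#' @export
ncp_layer_names <- function() {
  list(local = c("nitrogen_retention", "sediment_retention", "pollination",
                 "fodder", "commercial_timber", "domestic_timber",
                 "fuelwood", "flood_regulation", "nature_access",
                 "riverine_fish", "marine_fish", "reef_tourism",
                 "coastal_protection"),
       global = c("carbon_storage", "moisture_recycling"))
}
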