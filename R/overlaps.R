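#' Species representation-target rules
#'
#' Two rules for the fraction of a species' area of habitat (AOH) that a
#' solution must cover for the species to count as represented:
#' `log_linear` (full coverage below a lower range-size threshold, 10%
#' above an upper threshold, log-linear interpolation between) and
#' `minimum_area` (a Red-List-style persistence floor:
#' `min(1, min_area / range_area)`).
#'
#' @param kind `"log_linear"` or `"minimum_area"`.
#' @param lower_threshold_km2,upper_threshold_km2 log-linear endpoints
#'   (defaults 1,000 and 250,000 km2, the common representation-target
#'   convention; configurable).
#' @param lower_fraction,upper_fraction target fractions at/beyond the
#'   endpoints (defaults 1.0 and 0.1).
#' @param min_area_km2 persistence floor for the minimum-area rule.
#' @return object of class `representation_rule`.
#' @export
representation_rule <- function(kind = c("log_linear", "minimum_area"),
                                lower_threshold_km2 = 1000,
                                upper_threshold_km2 = 250000,
                                lower_fraction = 1.0, upper_fraction = 0.1,
                                min_area_km2 = 10) {
  kind <- match.arg(kind)
  if (lower_threshold_km2 >= upper_threshold_km2) {
    stop("lower threshold must be below upper threshold")
  }
  stopifnot(lower_fraction >= 0, lower_fraction <= 1,
            upper_fraction >= 0, upper_fraction <= 1, min_area_km2 > 0)
  structure(list(kind = kind, lower_threshold_km2 = lower_threshold_km2,
                 upper_threshold_km2 = upper_threshold_km2,
                 lower_fraction = lower_fraction,
                 upper_fraction = upper_fraction,
                 min_area_km2 = min_area_km2),
            class = "representation_rule")
}

#' Representation target for a given range size
#'
#' @param range_area_km2 species range area (> 0); vectorised.
#' @param rule a [representation_rule()].
#' @return target fraction(s) in `[0, 1]`.
#' @export
representation_target <- function(range_area_km2, rule) {
  if (any(range_area_km2 <= 0)) {
    stop("parameter error: range area must be positive")
  }
  if (rule$kind == "minimum_area") {
    return(pmin(1, rule$min_area_km2 / range_area_km2))
  }
  la <- log(range_area_km2)
  l0 <- log(rule$lower_threshold_km2)
  l1 <- log(rule$upper_threshold_km2)
  w <- pmin(1, pmax(0, (la - l0) / (l1 - l0)))
  rule$lower_fraction + w * (rule$upper_fraction - rule$lower_fraction)
}

#' Species AOH coverage by a solution
#'
#' A species is met when the area of its AOH inside the solution reaches
#' its representation target times its range area (`>=`, equality counts).
#' A target is flagged unachievable when it demands more area than the
#' mapped AOH itself contains.
#'
#' @param overlays an `overlay_bundle`.
#' @param solution_mask logical matrix.
#' @param rule a [representation_rule()].
#' @return list with `n_met`, `fraction_met`, `n_unachievable` and a
#'   per-species data frame `table`.
#' @export
species_coverage <- function(overlays, solution_mask, rule) {
  cell_area <- overlays$grid$cell_area_km2
  rows <- lapply(overlays$species, function(sp) {
    target_frac <- representation_target(sp$range_area_km2, rule)
    target_km2 <- target_frac * sp$range_area_km2
    aoh_km2 <- sum(sp$aoh_mask) * cell_area
    covered <- sum(sp$aoh_mask & solution_mask) * cell_area
    data.frame(species_id = sp$species_id,
               range_area_km2 = sp$range_area_km2,
               target_fraction = target_frac,
               covered_km2 = covered,
               met = covered >= target_km2 - 1e-9,
               unachievable = target_km2 > aoh_km2 + 1e-9)
  })
  tbl <- do.call(rbind, rows)
  if (is.null(tbl)) {
    return(list(n_met = 0L, fraction_met = NaN, n_unachievable = 0L,
                table = data.frame()))
  }
  list(n_met = sum(tbl$met), fraction_met = mean(tbl$met),
       n_unachievable = sum(tbl$unachievable), table = tbl)
}

#' Languages partially intersecting a solution
#'
#' A language counts as intersecting when at least one cell of its extent
#' is selected.
#'
#' @param overlays an `overlay_bundle`.
#' @param solution_mask logical matrix.
#' @return list with `n_intersecting` and `fraction`.
#' @export
language_coverage <- function(overlays, solution_mask) {
  hits <- vapply(overlays$languages, function(l)
    any(l$extent_mask & solution_mask), logical(1))
  list(n_intersecting = sum(hits),
       fraction = if (length(hits)) mean(hits) else NaN)
}

#' Partition land into local-only / global-only / both critical assets
#'
#' Exact three-way partition of the two solution footprints, with areas
#' and shares of total land area; the union share is the combined
#' critical-natural-asset share of land.
#'
#' @param local_mask,global_mask logical matrices on a common grid.
#' @param land_area_km2 total land area for the percentage base.
#' @param cell_area_km2 area of one cell.
#' @return data frame with rows local_only, global_only, both, union:
#'   `cells`, `area_km2`, `pct_of_land`.
#' @export
partition_local_global <- function(local_mask, global_mask, land_area_km2,
                                   cell_area_km2) {
  lo <- sum(local_mask & !global_mask)
  go <- sum(global_mask & !local_mask)
  bo <- sum(local_mask & global_mask)
  un <- lo + go + bo
  cells <- c(local_only = lo, global_only = go, both = bo, union = un)
  data.frame(component = names(cells), cells = as.integer(cells),
             area_km2 = cells * cell_area_km2,
             pct_of_land = 100 * cells * cell_area_km2 / land_area_km2,
             row.names = NULL)
}

#' Share of a reference mask covered by a subject mask
#'
#' `100 * area(subject intersect reference) / area(reference)` — e.g. the
#' protected share of critical natural assets.
#'
#' @param subject_mask,reference_mask logical matrices on a common grid.
#' @return percentage scalar.
#' @export
mask_share <- function(subject_mask, reference_mask) {
  nref <- sum(reference_mask)
  if (nref == 0) stop("undefined: empty reference mask")
  100 * sum(subject_mask & reference_mask) / nref
}
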