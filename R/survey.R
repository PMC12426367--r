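# Design-based biomass indices from stratified random trawl surveys.
#
# The estimator expands the mean catch density (catch / swept area) within
# each depth stratum by the stratum's area and sums across strata; it is a
# stand-in for model-based spatiotemporal indices, producing the same
# downstream month x species index panels.

#' Stratified design-based biomass index
#'
#' @param hauls data frame for one region-species-month with columns
#'   `stratum`, `catch_kg`, `swept_km2` (swept area > 0).
#' @param stratum_areas named numeric vector of stratum areas (km^2), names
#'   matching the `stratum` codes.
#' @return list with `index` (kg), `se` (kg, `NA` when no stratum has two
#'   or more hauls) and `flags` (character: empty strata with positive
#'   area contribute zero and are flagged `empty:<s>`; single-haul strata
#'   contribute no variance and are flagged `single_haul:<s>`).
#' @export
stratified_index <- function(hauls, stratum_areas) {
  stopifnot(all(c("stratum", "catch_kg", "swept_km2") %in% names(hauls)),
            !is.null(names(stratum_areas)), all(stratum_areas > 0))
  if (nrow(hauls) && any(hauls$swept_km2 <= 0)) {
    stop_validation("swept area must be positive", code = "bad_swept")
  }
  if (nrow(hauls) && any(hauls$catch_kg < 0)) {
    stop_validation("catch must be non-negative", code = "bad_catch")
  }
  idx <- 0; v <- 0; flags <- character(0); any_var <- FALSE
  for (s in names(stratum_areas)) {
    a <- stratum_areas[[s]]
    d <- hauls[hauls$stratum == s, , drop = FALSE]
    if (!nrow(d)) {
      flags <- c(flags, paste0("empty:", s))
      next
    }
    dens <- d$catch_kg / d$swept_km2
    idx <- idx + a * mean(dens)
    if (nrow(d) >= 2L) {
      v <- v + a^2 * var(dens) / nrow(d)   # (n_s - 1) denominator via var()
      any_var <- TRUE
    } else {
      flags <- c(flags, paste0("single_haul:", s))
    }
  }
  if (length(flags[startsWith(flags, "empty")])) {
    warning("strata with positive area but no hauls: ",
            paste(flags[startsWith(flags, "empty")], collapse = ", "))
  }
  list(index = idx, se = if (any_var) sqrt(v) else NA_real_, flags = flags)
}

#' Batch stratified indices over species, years and months
#'
#' @param hauls haul records with columns `year`, `month`, `species`,
#'   `stratum`, `catch_kg`, `swept_km2` (and optionally `region`).
#' @param stratum_areas named stratum areas (km^2).
#' @param region region label stamped on the output.
#' @return data frame of `BiomassIndex` rows: `region`, `species`, `year`,
#'   `month`, `index`, `se`, `flags`.
#' @export
survey_biomass_index <- function(hauls, stratum_areas, region = "R1") {
  keys <- unique(hauls[c("species", "year", "month")])
  keys <- keys[order(keys$species, keys$year, keys$month), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- hauls$species == keys$species[i] & hauls$year == keys$year[i] &
      hauls$month == keys$month[i]
    est <- suppressWarnings(stratified_index(hauls[sel, , drop = FALSE],
                                             stratum_areas))
    data.frame(region = region, species = keys$species[i],
               year = keys$year[i], month = keys$month[i],
               index = est$index, se = est$se,
               flags = paste(est$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Convert biomass-index rows to long biomass records
#'
#' @param index output of [survey_biomass_index()].
#' @return long records with `quantity_kind = "biomass_kg"`.
#' @export
index_to_long <- function(index) {
  validate_long(data.frame(
    region = index$region, year = index$year, month = index$month,
    species = index$species, quantity_kind = "biomass_kg",
    value = pmax(index$index, 0), stringsAsFactors = FALSE
  ))
}

#' Regular prediction grid over a rectangular hull
#'
#' @param xlim,ylim planar bounds (km).
#' @param cell_area cell area in km^2 (default 6.25, i.e., 2.5 km cells).
#' @return data frame of cell centroids `x`, `y` with attribute
#'   `cell_area`.
#' @export
make_grid <- function(xlim, ylim, cell_area = 6.25) {
  side <- sqrt(cell_area)
  xs <- seq(xlim[1L] + side / 2, xlim[2L], by = side)
  ys <- seq(ylim[1L] + side / 2, ylim[2L], by = side)
  g <- expand.grid(x = xs, y = ys)
  attr(g, "cell_area") <- cell_area
  g
}

#' Area-weighted aggregation of a density surface over a grid
#'
#' Sums `density(centroid) * cell_area` across grid cells; with the default
#' 6.25 km^2 cells this mirrors area-weighted index construction from a
#' model-predicted surface.
#'
#' @param surface function of `(x, y)` vectors returning density (kg/km^2).
#' @param grid grid from [make_grid()] (or any data frame of centroids with
#'   a `cell_area` attribute or explicit `cell_area` argument).
#' @param cell_area cell area override (km^2).
#' @return total kg over the grid.
#' @export
grid_aggregate <- function(surface, grid, cell_area = attr(grid, "cell_area")) {
  if (is.null(cell_area)) cell_area <- 6.25
  dens <- surface(grid$x, grid$y)
  stopifnot(length(dens) == nrow(grid))
  sum(dens * cell_area)
}
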