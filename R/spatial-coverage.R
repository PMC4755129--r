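#' Coverage statistics for important sites and protected areas
#'
#' Per spatial unit, this module reports (i) the number and mean size of
#' important sites (IBAs / AZE sites), and the percentage of the unit's
#' surface covered by the dissolved site layer, and (ii) the percentage of
#' the unit's land and sea covered by dissolved protected areas. Dissolving
#' first means overlapping polygons are never double counted.
#'
#' A site is *counted* in the single unit that contains its representative
#' interior point, so counts stay integers even when a site straddles a
#' boundary; percentage coverage, by contrast, always uses the true
#' geometric intersection of the dissolved layer with each unit.
#'
#' @name spatial_coverage
#' @keywords internal
NULL

#' Assemble unit geometries
#'
#' @param unit character vector of unit labels.
#' @param land,sea lists of rectsets, one per unit (use [rectset()] with no
#'   arguments for a missing realm). Land and sea of a unit must not
#'   overlap.
#' @return data frame with `unit`, `land`, `sea` list-columns.
#' @export
unit_geometry <- function(unit, land, sea) {
  stopifnot(length(unit) == length(land), length(unit) == length(sea))
  for (i in seq_along(unit)) {
    if (rs_area(rs_intersect(land[[i]], sea[[i]])) > 0) {
      stop("land and sea geometries overlap for unit: ", unit[i],
           call. = FALSE)
    }
  }
  data.frame(unit = as.character(unit),
             land = I(land), sea = I(sea),
             stringsAsFactors = FALSE)
}

unit_total_geom <- function(unit_geoms, i) {
  dissolve(unit_geoms$land[[i]], unit_geoms$sea[[i]])
}

#' Site coverage statistics per unit
#'
#' @param sites data frame with columns `site_id`, `site_type` and a
#'   `geometry` list-column of rectsets.
#' @param unit_geoms a [unit_geometry()] table.
#' @param site_type which site type to tabulate (`"IBA"` or `"AZE"`).
#' @return data frame with columns `unit`, `site_type`, `n_sites`,
#'   `mean_size_km2` (`NA` when no sites) and `pct_cover` in `[0, 100]`
#'   (`NA` when the unit has no surface).
#' @export
site_coverage <- function(sites, unit_geoms, site_type = c("IBA", "AZE")) {
  site_type <- match.arg(site_type)
  stopifnot(is.data.frame(sites), is.data.frame(unit_geoms))
  sel <- sites[sites$site_type == site_type, , drop = FALSE]
  # representative point of each site, for unit assignment
  reps <- lapply(sel$geometry, rs_rep_point)
  site_area <- vapply(sel$geometry, rs_area, numeric(1))
  out <- vector("list", nrow(unit_geoms))
  for (i in seq_len(nrow(unit_geoms))) {
    total <- unit_total_geom(unit_geoms, i)
    in_unit <- vapply(reps, function(p) {
      rs_contains_point(total, p["x"], p["y"])
    }, logical(1))
    n <- sum(in_unit)
    mean_size <- if (n > 0) mean(site_area[in_unit]) else NA_real_
    denom <- rs_area(total)
    pct <- if (denom > 0) {
      merged <- dissolve(sel$geometry)
      100 * rs_area(rs_intersect(merged, total)) / denom
    } else {
      NA_real_
    }
    out[[i]] <- data.frame(unit = unit_geoms$unit[i], site_type = site_type,
                           n_sites = as.integer(n),
                           mean_size_km2 = mean_size, pct_cover = pct,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Protected-area coverage of land and sea per unit
#'
#' Terrestrial protected areas are dissolved into one layer and intersected
#' with each unit's land; marine protected areas with its sea.
#'
#' @param pas data frame with columns `pa_id`, `realm` (`"terrestrial"` or
#'   `"marine"`) and a `geometry` list-column of rectsets. Point-only
#'   records (empty geometry) are excluded from coverage with a message.
#' @param unit_geoms a [unit_geometry()] table.
#' @return data frame with columns `unit`, `pct_land`, `pct_sea` (`NA`
#'   where the unit has no land or no sea).
#' @export
pa_coverage <- function(pas, unit_geoms) {
  stopifnot(is.data.frame(pas), is.data.frame(unit_geoms))
  empty <- vapply(pas$geometry, rs_is_empty, logical(1))
  if (any(empty)) {
    message("excluding ", sum(empty),
            " protected area(s) without polygon geometry from coverage")
    pas <- pas[!empty, , drop = FALSE]
  }
  land_layer <- dissolve(pas$geometry[pas$realm == "terrestrial"])
  sea_layer <- dissolve(pas$geometry[pas$realm == "marine"])
  pct_of <- function(layer, geom) {
    denom <- rs_area(geom)
    if (denom > 0) 100 * rs_area(rs_intersect(layer, geom)) / denom
    else NA_real_
  }
  out <- vector("list", nrow(unit_geoms))
  for (i in seq_len(nrow(unit_geoms))) {
    out[[i]] <- data.frame(
      unit = unit_geoms$unit[i],
      pct_land = pct_of(land_layer, unit_geoms$land[[i]]),
      pct_sea = pct_of(sea_layer, unit_geoms$sea[[i]]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
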