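#' Trends in site protection with missing establishment dates
#'
#' For each year, the indicator is the percentage of sites (IBAs or AZE
#' sites) wholly covered by the union of protected areas already
#' established by that year. "Wholly covered" means the dissolved active
#' protected-area layer overlaps at least a configurable threshold of the
#' site's area (default 0.98, tolerating boundary-digitization slivers; use
#' 1 for strict containment).
#'
#' Establishment dates are missing for part of the protected-area estate.
#' Each undated protected area is assigned a year drawn uniformly (with
#' replacement) from the dated protected areas of the same country and
#' realm; where a country has fewer than five dated protected areas of
#' that realm, the draw falls back to the pool of all dated protected
#' areas of the realm. Repeating the assignment many times yields a
#' distribution of trend series, summarized by the per-year median and the
#' 2.5th/97.5th percentiles (a 95% confidence envelope).
#'
#' @name pa_trend
#' @keywords internal
NULL

#' Precompute per-site protected-area overlap profiles
#'
#' For each site, caches the site-clipped geometry of every protected area
#' that overlaps it. Because clipping distributes over union, the union of
#' the cached clipped geometries of any active subset equals the clip of
#' the dissolved active layer: per-year coverage can then be recomputed
#' from the cache without touching the full layers again.
#'
#' @param sites data frame with `site_id`, `site_type`, `geometry`
#'   list-column of rectsets.
#' @param pas data frame with `pa_id`, `realm`, `year_established`
#'   (NA = undated), `geometry` list-column.
#' @return list of profiles; each has `site_id`, `site_type`, `area`,
#'   `pa_id` (character vector) and `clip` (list of rectsets), `fraction`
#'   (overlap fraction of site area per PA).
#' @export
site_protection_profiles <- function(sites, pas) {
  stopifnot(is.data.frame(sites), is.data.frame(pas))
  lapply(seq_len(nrow(sites)), function(i) {
    g <- sites$geometry[[i]]
    a <- rs_area(g)
    clips <- lapply(pas$geometry, function(pg) rs_intersect(pg, g))
    keep <- !vapply(clips, rs_is_empty, logical(1))
    list(site_id = as.character(sites$site_id[i]),
         site_type = as.character(sites$site_type[i]),
         area = a,
         pa_id = as.character(pas$pa_id)[keep],
         clip = clips[keep],
         fraction = vapply(clips[keep], rs_area, numeric(1)) / a)
  })
}

# numerical slack on the coverage ratio: areas are exact up to double
# rounding, so a site covered exactly to the threshold must not flip
.cover_eps <- 1e-9

#' Is a site wholly covered by a set of active protected areas?
#'
#' @param profile one element of [site_protection_profiles()].
#' @param active_pa_ids character vector of active protected-area ids.
#' @param threshold fraction of site area that must be overlapped,
#'   in (0, 1].
#' @return logical.
#' @export
site_wholly_covered <- function(profile, active_pa_ids, threshold = 0.98) {
  stopifnot(threshold > 0, threshold <= 1)
  idx <- which(profile$pa_id %in% active_pa_ids)
  if (length(idx) == 0) return(FALSE)
  covered <- rs_area(dissolve(profile$clip[idx]))
  covered / profile$area >= threshold - .cover_eps
}

# first year at which the site's covered fraction reaches the threshold,
# given a complete year assignment (named by pa_id); Inf if never
first_cover_year <- function(profile, years_by_pa, threshold) {
  if (length(profile$pa_id) == 0) return(Inf)
  yrs <- years_by_pa[profile$pa_id]
  if (anyNA(yrs)) {
    stop("undated protected area(s) reached coverage computation; ",
         "impute years first", call. = FALSE)
  }
  o <- order(yrs)
  target <- (threshold - .cover_eps) * profile$area
  acc <- NULL
  uy <- unique(sort(yrs))
  for (y in uy) {
    add <- profile$clip[o[yrs[o] <= y]]
    acc <- dissolve(add)  # cached clips are few; recompute is cheap
    if (rs_area(acc) >= target) return(y)
  }
  Inf
}

#' Build establishment-year imputation pools
#'
#' One pool per (country, realm) holding the dated establishment years of
#' that country and realm; countries with fewer than `min_dated` dated
#' protected areas of a realm fall back to the pool of all dated years of
#' that realm.
#'
#' @param pas protected-area table (`pa_id`, `country_code`, `realm`,
#'   `year_established` with NA for undated).
#' @param min_dated minimum dated count for a country-level pool
#'   (default 5).
#' @return object of class `imputation_pools`.
#' @export
imputation_pools <- function(pas, min_dated = 5) {
  stopifnot(is.data.frame(pas))
  dated <- pas[!is.na(pas$year_established), , drop = FALSE]
  realms <- c("terrestrial", "marine")
  realm_pool <- lapply(stats::setNames(realms, realms), function(r) {
    as.numeric(dated$year_established[dated$realm == r])
  })
  country_pool <- list()
  if (nrow(dated) > 0) {
    key <- paste(dated$country_code, dated$realm, sep = "|")
    country_pool <- split(as.numeric(dated$year_established), key)
  }
  structure(list(country_pool = country_pool, realm_pool = realm_pool,
                 min_dated = min_dated),
            class = "imputation_pools")
}

pool_for <- function(pools, country, realm) {
  key <- paste(country, realm, sep = "|")
  p <- pools$country_pool[[key]]
  if (!is.null(p) && length(p) >= pools$min_dated) return(p)
  pools$realm_pool[[realm]]
}

#' Impute establishment years for undated protected areas
#'
#' Each undated protected area receives a year drawn uniformly with
#' replacement from its pool (see [imputation_pools()]); dated records are
#' never altered. Draws consume the current RNG stream; call
#' `set.seed()` beforehand (or use [trend_with_ci()], which manages the
#' seed) for reproducibility.
#'
#' @param pas protected-area table.
#' @param pools an [imputation_pools()] object (built from `pas` when
#'   omitted).
#' @return `pas` with `year_established` completed.
#' @export
impute_years <- function(pas, pools = imputation_pools(pas)) {
  und <- which(is.na(pas$year_established))
  for (i in und) {
    p <- pool_for(pools, pas$country_code[i], pas$realm[i])
    if (length(p) == 0) {
      stop("no dated protected areas in realm '", pas$realm[i],
           "': imputation impossible", call. = FALSE)
    }
    pas$year_established[i] <- p[sample.int(length(p), 1)]
  }
  pas
}

#' Percentage of sites wholly covered, per year
#'
#' @param sites site table (see [site_protection_profiles()]); all sites in
#'   the table enter the denominator.
#' @param pas protected-area table with complete `year_established`.
#' @param years integer vector of calendar years (ascending).
#' @param threshold coverage threshold in (0, 1].
#' @param profiles optional precomputed [site_protection_profiles()].
#' @return numeric vector of percentages, one per year, non-decreasing.
#' @export
coverage_series <- function(sites, pas, years, threshold = 0.98,
                            profiles = NULL) {
  if (nrow(sites) == 0) {
    return(rep(NA_real_, length(years)))
  }
  if (is.null(profiles)) profiles <- site_protection_profiles(sites, pas)
  yrs <- stats::setNames(as.numeric(pas$year_established),
                         as.character(pas$pa_id))
  fcy <- vapply(profiles, first_cover_year, numeric(1),
                years_by_pa = yrs, threshold = threshold)
  vapply(years, function(y) 100 * mean(fcy <= y), numeric(1))
}

#' Monte Carlo trend of site protection with a 95% envelope
#'
#' Repeats the establishment-year imputation `n_reps` times, recomputes
#' the coverage series for each replicate, and summarizes per year by the
#' median and the 2.5th/97.5th empirical percentiles (linear
#' interpolation). With no undated protected areas every replicate is
#' identical and the envelope collapses onto the median.
#'
#' @inheritParams coverage_series
#' @param n_reps number of imputation replicates (default 1000).
#' @param seed optional integer seed; identical seed and inputs give an
#'   identical result.
#' @param keep_replicates retain the replicate matrix (rows = replicates)?
#' @return object of class `coverage_trend` with elements `years`,
#'   `median_pct`, `ci_low`, `ci_high`, `n_sites`, `n_reps`, `threshold`.
#' @export
trend_with_ci <- function(sites, pas, years, n_reps = 1000,
                          threshold = 0.98, seed = NULL,
                          keep_replicates = FALSE) {
  stopifnot(n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  profiles <- site_protection_profiles(sites, pas)
  pools <- imputation_pools(pas)
  undated_ids <- as.character(pas$pa_id[is.na(pas$year_established)])
  known_years <- stats::setNames(as.numeric(pas$year_established),
                                 as.character(pas$pa_id))

  # sites untouched by any undated PA have a fixed first-cover year
  touches_undated <- vapply(profiles, function(p) {
    any(p$pa_id %in% undated_ids)
  }, logical(1))
  fixed_fcy <- rep(NA_real_, length(profiles))
  for (i in which(!touches_undated)) {
    fixed_fcy[i] <- first_cover_year(profiles[[i]], known_years, threshold)
  }

  n_sites <- length(profiles)
  reps <- matrix(NA_real_, nrow = n_reps, ncol = length(years))
  for (r in seq_len(n_reps)) {
    yrs <- known_years
    for (id in undated_ids) {
      i <- match(id, as.character(pas$pa_id))
      p <- pool_for(pools, pas$country_code[i], pas$realm[i])
      if (length(p) == 0) {
        stop("no dated protected areas in realm '", pas$realm[i],
             "': imputation impossible", call. = FALSE)
      }
      yrs[id] <- p[sample.int(length(p), 1)]
    }
    fcy <- fixed_fcy
    for (i in which(touches_undated)) {
      fcy[i] <- first_cover_year(profiles[[i]], yrs, threshold)
    }
    reps[r, ] <- vapply(years, function(y) 100 * mean(fcy <= y), numeric(1))
  }
  q <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE, type = 7)
  structure(list(years = as.numeric(years),
                 median_pct = q[2, ], ci_low = q[1, ], ci_high = q[3, ],
                 n_sites = n_sites, n_reps = n_reps, threshold = threshold,
                 replicates = if (keep_replicates) reps else NULL),
            class = "coverage_trend")
}

#' @export
print.coverage_trend <- function(x, ...) {
  cat("Protected-area coverage trend: ", x$n_sites, " site(s), ",
      x$n_reps, " replicate(s), threshold ", x$threshold, "\n", sep = "")
  last <- length(x$years)
  cat(sprintf("  %g: median %.1f%% [%.1f, %.1f]\n",
              x$years[1], x$median_pct[1], x$ci_low[1], x$ci_high[1]))
  cat(sprintf("  %g: median %.1f%% [%.1f, %.1f]\n",
              x$years[last], x$median_pct[last], x$ci_low[last],
              x$ci_high[last]))
  invisible(x)
}

#' @export
as.data.frame.coverage_trend <- function(x, ...) {
  data.frame(year = x$years, median_pct = x$median_pct,
             ci_low = x$ci_low, ci_high = x$ci_high)
}

#' Plot a coverage trend as a line with its 95% envelope
#' @param x a `coverage_trend`.
#' @param y ignored.
#' @param ... passed to [plot()].
#' @export
plot.coverage_trend <- function(x, y, ...) {
  plot(x$years, x$median_pct, type = "n", ylim = c(0, 100),
       xlab = "Year", ylab = "% of sites wholly covered", ...)
  graphics::polygon(c(x$years, rev(x$years)), c(x$ci_low, rev(x$ci_high)),
                    col = "grey85", border = NA)
  graphics::lines(x$years, x$median_pct, lwd = 2)
  invisible(x)
}
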