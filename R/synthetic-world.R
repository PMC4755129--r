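#' Synthetic world generator with recorded ground truth
#'
#' Builds a self-contained planar world -- countries, two alternative
#' regionalizations, species with country-coded occurrences and Red List
#' categories, genuine category-change histories, range fractions,
#' important sites and protected areas -- together with the true value of
#' every downstream statistic, computed by direct enumeration during
#' generation. Every stage of the pipeline can therefore be validated
#' without any licensed global dataset.
#'
#' The world is a row of unit-square country cells along the x axis; the
#' lower half of each cell is land, the upper half sea, and a sea-only
#' strip beyond the last country represents ABNJ (the high seas). Regions
#' and subregions are contiguous blocks of countries, so most multi-country
#' ranges stay within a single region -- mirroring the dominance of
#' single-region endemism in real assessments. All coordinates are small
#' rationals: areas are exact. Two regionalizations with different block
#' boundaries play the role that alternative assessment-process
#' regionalizations (such as GEO and IPBES) play for real data.
#'
#' @name synthetic_data
#' @keywords internal
NULL

# independent RNG substreams derived from one master seed, so adding a
# component never shifts the draws of another
substream_seed <- function(seed, component) {
  offset <- c(species = 11, occurrences = 23, changes = 37,
              sites = 53, pas = 71, masking = 97)[[component]]
  (as.integer(seed) + offset * 1000003L) %% 2147483629L
}

#' Specification of a synthetic world
#'
#' Defaults describe a desk-scale world with the statistical structure the
#' pipeline assumes: several taxonomic groups with a realistic Red List
#' category mixture including a substantial Data Deficient share, mostly
#' single-region species ranges, overlapping site and protected-area
#' rectangles, and undated protected-area fractions of 14.3% (terrestrial)
#' and 8.6% (marine).
#'
#' @param n_countries number of country cells.
#' @param schemes named list of regionalizations; each element is
#'   `c(n_regions = ..., n_subregions_per_region = ...)`. Countries are
#'   assigned to subregions as contiguous equal blocks.
#' @param groups taxonomic group labels.
#' @param n_species_per_group species per group.
#' @param category_mix named probabilities over
#'   EX, EW, CR, EN, VU, NT, DD, LC (must sum to 1).
#' @param pe_flag_prob probability a CR species carries a Possibly Extinct
#'   flag.
#' @param endemism_prob probability a species is confined to a single
#'   country.
#' @param mean_range_countries mean number of countries in a multi-country
#'   range (consecutive cells).
#' @param abnj_prob probability a species additionally occurs in ABNJ.
#' @param noise_origin_prob probability a species gets one extra
#'   occurrence record of an excluded origin (vagrant / uncertain /
#'   introduced) in a country outside its true range.
#' @param change_rate mean number of genuine category changes per species.
#' @param deterioration_prob probability a genuine change increases
#'   extinction risk.
#' @param nongenuine_rate mean number of non-genuine recorded changes per
#'   species (these must not move any index).
#' @param period an [assessment_period()] (default 1993--2013).
#' @param n_iba,n_aze site counts per type.
#' @param n_pas number of protected areas.
#' @param pa_year_range calendar-year range establishment years are drawn
#'   from.
#' @param undated_pa_fraction named fractions of protected areas whose
#'   establishment year is masked, per realm.
#' @param seed master seed; all component substreams derive from it.
#' @return object of class `world_spec`.
#' @export
world_spec <- function(n_countries = 24,
                       schemes = list(
                         SYNA = c(n_regions = 4,
                                  n_subregions_per_region = 2),
                         SYNB = c(n_regions = 3,
                                  n_subregions_per_region = 2)),
                       groups = c("mammals", "birds", "amphibians"),
                       n_species_per_group = 60,
                       category_mix = c(EX = 0.02, EW = 0.01, CR = 0.06,
                                        EN = 0.08, VU = 0.10, NT = 0.12,
                                        DD = 0.12, LC = 0.49),
                       pe_flag_prob = 0.1,
                       endemism_prob = 0.75,
                       mean_range_countries = 3,
                       abnj_prob = 0.05,
                       noise_origin_prob = 0.15,
                       change_rate = 0.25,
                       deterioration_prob = 0.75,
                       nongenuine_rate = 0.05,
                       period = assessment_period(1993, 2013),
                       n_iba = 40, n_aze = 15,
                       n_pas = 120,
                       pa_year_range = c(1960, 2010),
                       undated_pa_fraction = c(terrestrial = 0.143,
                                               marine = 0.086),
                       seed = 1L) {
  for (nm in names(schemes)) {
    n_sub <- schemes[[nm]][["n_regions"]] *
      schemes[[nm]][["n_subregions_per_region"]]
    if (n_countries < n_sub) {
      stop("infeasible spec: scheme ", nm,
           " has more subregions than countries", call. = FALSE)
    }
  }
  if (abs(sum(category_mix) - 1) > 1e-9) {
    stop("category_mix must sum to 1", call. = FALSE)
  }
  if (any(undated_pa_fraction < 0 | undated_pa_fraction >= 1)) {
    stop("undated_pa_fraction must lie in [0, 1)", call. = FALSE)
  }
  spec <- as.list(environment())
  spec$nm <- NULL
  spec$n_sub <- NULL
  structure(spec, class = "world_spec")
}

# deterministic ISO3-like codes AAA, AAB, AAC, ...
synthetic_iso3 <- function(n) {
  vapply(seq_len(n) - 1L, function(i) {
    paste0(LETTERS[i %/% 676 + 1], LETTERS[(i %/% 26) %% 26 + 1],
           LETTERS[i %% 26 + 1])
  }, character(1))
}

rank_to_category <- function(r) {
  c("LC", "NT", "VU", "EN", "CR", "EW")[r + 1]
}

# assign n cells to regions/subregions as contiguous blocks
synthetic_scheme_table <- function(n, scheme_name, n_regions,
                                   n_subregions_per_region) {
  n_sub <- n_regions * n_subregions_per_region
  sub_of_country <- sort(rep_len(seq_len(n_sub), n))
  region_of_sub <- rep(seq_len(n_regions), each = n_subregions_per_region)
  data.frame(
    country_name = paste0("Country ", seq_len(n)),
    iso3 = synthetic_iso3(n),
    region = paste0(scheme_name, " Region ",
                    region_of_sub[sub_of_country]),
    subregion = paste0(scheme_name, " Subregion ", sub_of_country),
    stringsAsFactors = FALSE)
}

#' Mask establishment years of a fraction of protected areas
#'
#' Per realm, `round(fraction * n)` protected areas lose their year, but
#' never so many that fewer than five dated ones remain (the country-pool
#' rule needs a dated reserve). The true years are returned alongside.
#'
#' @param pas protected-area table with complete `year_established`.
#' @param undated_fraction named fractions per realm
#'   (`terrestrial`, `marine`).
#' @param seed seed for the masking draw.
#' @return list with `pas` (years partly NA) and `true_years` (named by
#'   `pa_id`).
#' @export
mask_pa_years <- function(pas,
                          undated_fraction = c(terrestrial = 0.143,
                                               marine = 0.086),
                          seed = 1L) {
  stopifnot(!anyNA(pas$year_established))
  if (any(undated_fraction < 0 | undated_fraction >= 1)) {
    stop("undated fraction must lie in [0, 1)", call. = FALSE)
  }
  true_years <- stats::setNames(as.numeric(pas$year_established),
                                as.character(pas$pa_id))
  set.seed(seed)
  for (realm in names(undated_fraction)) {
    idx <- which(pas$realm == realm)
    n_mask <- round(undated_fraction[[realm]] * length(idx))
    n_mask <- min(n_mask, max(0L, length(idx) - 5L))
    if (n_mask > 0) {
      masked <- sample(idx, n_mask)
      pas$year_established[masked] <- NA_real_
    }
  }
  if (nrow(pas) > 0 && all(is.na(pas$year_established))) {
    stop("masking left no dated protected areas", call. = FALSE)
  }
  list(pas = pas, true_years = true_years)
}

#' Generate a synthetic world and its ground truth
#'
#' @param spec a [world_spec()].
#' @return list with the pipeline inputs (`schemes`, `assessments`,
#'   `occurrences`, `changes`, `fractions` per scheme and level, `sites`,
#'   `pas`, `unit_geoms` per scheme and level, `period`) and `truth`, the
#'   directly enumerated value of every downstream statistic (per-unit
#'   species, endemic and category counts, RLI contributions, coverage
#'   percentages, true establishment years, true trend series per site
#'   type).
#' @export
generate_world <- function(spec = world_spec()) {
  stopifnot(inherits(spec, "world_spec"))
  n <- spec$n_countries
  schemes <- lapply(names(spec$schemes), function(nm) {
    p <- spec$schemes[[nm]]
    region_scheme(
      synthetic_scheme_table(n, nm, p[["n_regions"]],
                             p[["n_subregions_per_region"]]),
      scheme_name = nm, special_units = "ABNJ")
  })
  names(schemes) <- names(spec$schemes)
  iso <- synthetic_iso3(n)

  ## ---- unit geometries: country i occupies [i-1, i] x [0, 1] ----------
  country_land <- lapply(seq_len(n), function(i) rectset(i - 1, 0, i, 0.5))
  country_sea <- lapply(seq_len(n), function(i) rectset(i - 1, 0.5, i, 1))
  abnj_sea <- rectset(n, 0.5, n + 2, 1)
  unit_geoms_for <- function(scheme, level) {
    units <- scheme_units(scheme, level)
    land <- lapply(units, function(u) {
      dissolve(country_land[match(scheme_members(scheme, u, level), iso)])
    })
    sea <- lapply(units, function(u) {
      dissolve(country_sea[match(scheme_members(scheme, u, level), iso)])
    })
    unit_geometry(c(units, "ABNJ"),
                  c(land, list(rectset())),
                  c(sea, list(abnj_sea)))
  }
  unit_geoms <- lapply(schemes, function(s) {
    list(region = unit_geoms_for(s, "region"),
         subregion = unit_geoms_for(s, "subregion"))
  })

  ## ---- species, categories, ranges ------------------------------------
  groups <- spec$groups
  n_sp <- length(groups) * spec$n_species_per_group
  species_id <- sprintf("sp%04d", seq_len(n_sp))
  group <- rep(groups, each = spec$n_species_per_group)

  set.seed(substream_seed(spec$seed, "species"))
  # initial (pre-change) categories; species with change histories get
  # their current category from the end of the walk below
  category <- if (n_sp > 0) {
    sample(names(spec$category_mix), n_sp, replace = TRUE,
           prob = spec$category_mix)
  } else character()

  # true range: consecutive run of countries, plus optional ABNJ
  range_units <- vector("list", n_sp)
  for (i in seq_len(n_sp)) {
    k <- if (stats::runif(1) < spec$endemism_prob) 1L else {
      min(n, 2L + stats::rpois(1, max(0, spec$mean_range_countries - 2)))
    }
    start <- sample.int(n - k + 1L, 1)
    units <- iso[start:(start + k - 1L)]
    if (stats::runif(1) < spec$abnj_prob) units <- c(units, "ABNJ")
    range_units[[i]] <- units
  }

  ## ---- occurrence records (true range + excluded-origin noise) --------
  set.seed(substream_seed(spec$seed, "occurrences"))
  occ_rows <- vector("list", n_sp)
  for (i in seq_len(n_sp)) {
    u <- range_units[[i]]
    rows <- data.frame(species_id = species_id[i], unit_code = u,
                       origin = "native", stringsAsFactors = FALSE)
    if (stats::runif(1) < spec$noise_origin_prob) {
      outside <- setdiff(iso, u)
      if (length(outside) > 0) {
        rows <- rbind(rows, data.frame(
          species_id = species_id[i],
          unit_code = sample(outside, 1),
          origin = sample(c("vagrant", "uncertain", "introduced"), 1),
          stringsAsFactors = FALSE))
      }
    }
    occ_rows[[i]] <- rows
  }
  occurrences <- if (n_sp > 0) do.call(rbind, occ_rows) else
    data.frame(species_id = character(), unit_code = character(),
               origin = character(), stringsAsFactors = FALSE)
  rownames(occurrences) <- NULL

  ## ---- range fractions (equal weight per occupied cell) ---------------
  fraction_table <- function(scheme, level) {
    rows <- vector("list", n_sp)
    for (i in seq_len(n_sp)) {
      u <- range_units[[i]]
      lab <- vapply(u, function(code) {
        if (code == "ABNJ") "ABNJ" else unit_of(scheme, code, level)
      }, character(1))
      w <- tapply(rep(1 / length(u), length(u)), lab, sum)
      rows[[i]] <- data.frame(species_id = species_id[i],
                              unit = names(w), fraction = as.numeric(w),
                              stringsAsFactors = FALSE)
    }
    out <- if (n_sp > 0) do.call(rbind, rows) else
      data.frame(species_id = character(), unit = character(),
                 fraction = numeric(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  }
  fractions <- lapply(schemes, function(s) {
    list(region = fraction_table(s, "region"),
         subregion = fraction_table(s, "subregion"))
  })

  ## ---- genuine category-change histories ------------------------------
  set.seed(substream_seed(spec$seed, "changes"))
  rankable <- !category %in% c("DD", "NE")
  change_rows <- list()
  net_steps <- stats::setNames(numeric(n_sp), species_id)
  for (i in seq_len(n_sp)) {
    if (!rankable[i]) next
    m <- stats::rpois(1, spec$change_rate)
    if (m == 0) next
    # walk the category ladder forward in time from the initial category,
    # with the configured deterioration bias; the ladder ends are
    # reflecting (an LC species cannot improve, an EX one cannot worsen)
    r <- category_rank(category[i], "none")
    steps <- integer(m)
    ranks <- numeric(m + 1)
    ranks[1] <- r
    for (j in seq_len(m)) {
      worsen <- stats::runif(1) < spec$deterioration_prob
      if (r == 5) worsen <- FALSE
      if (r == 0) worsen <- TRUE
      steps[j] <- if (worsen) -1L else 1L
      r <- r - steps[j]   # risk increase (-1 step) moves the rank up
      ranks[j + 1] <- r
    }
    category[i] <- if (r == 5) {
      if (ranks[1] == 5) category[i] else
        sample(c("EW", "EX"), 1)
    } else {
      rank_to_category(r)
    }
    for (j in seq_len(m)) {
      change_rows[[length(change_rows) + 1]] <- data.frame(
        species_id = species_id[i], group = group[i],
        cat_start = rank_to_category(ranks[j]),
        cat_end = rank_to_category(ranks[j + 1]),
        flag_start = "none", flag_end = "none",
        genuine = TRUE, stringsAsFactors = FALSE)
    }
    net_steps[i] <- sum(steps)
    # occasional non-genuine recorded change: must not move anything
    if (stats::runif(1) < spec$nongenuine_rate) {
      change_rows[[length(change_rows) + 1]] <- data.frame(
        species_id = species_id[i], group = group[i],
        cat_start = "LC", cat_end = "NT",
        flag_start = "none", flag_end = "none",
        genuine = FALSE, stringsAsFactors = FALSE)
    }
  }
  changes <- if (length(change_rows) > 0) do.call(rbind, change_rows) else
    data.frame(species_id = character(), group = character(),
               cat_start = character(), cat_end = character(),
               flag_start = character(), flag_end = character(),
               genuine = logical(), stringsAsFactors = FALSE)
  rownames(changes) <- NULL

  # Possibly Extinct flags attach to CR assessments with no recorded walk
  # (a flagged CR ranks at the EW/EX level, which the walk tracks itself)
  flag <- unname(ifelse(category == "CR" & net_steps == 0 &
                          stats::runif(n_sp) < spec$pe_flag_prob,
                        "PE", "none"))
  assessments <- data.frame(species_id = species_id, group = group,
                            category = category, flag = flag,
                            stringsAsFactors = FALSE)
  rownames(assessments) <- NULL

  ## ---- sites -----------------------------------------------------------
  set.seed(substream_seed(spec$seed, "sites"))
  make_sites <- function(n_sites, type, prefix) {
    if (n_sites == 0) {
      return(data.frame(site_id = character(), site_type = character(),
                        realm = character(), xmin = numeric(),
                        ymin = numeric(), xmax = numeric(),
                        ymax = numeric(), stringsAsFactors = FALSE))
    }
    rows <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      cty <- sample.int(n, 1)
      marine <- stats::runif(1) < 0.25
      y_lo <- if (marine) 0.5 else 0
      w <- stats::runif(1, 0.08, 0.3)
      h <- stats::runif(1, 0.08, 0.3)
      x0 <- (cty - 1) + stats::runif(1, 0, 1 - w)
      y0 <- y_lo + stats::runif(1, 0, 0.5 - h)
      rows[[i]] <- data.frame(
        site_id = sprintf("%s%03d", prefix, i), site_type = type,
        realm = if (marine) "marine" else "terrestrial",
        xmin = x0, ymin = y0, xmax = x0 + w, ymax = y0 + h,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  site_tab <- rbind(make_sites(spec$n_iba, "IBA", "iba"),
                    make_sites(spec$n_aze, "AZE", "aze"))
  sites <- data.frame(site_id = site_tab$site_id,
                      site_type = site_tab$site_type,
                      realm = site_tab$realm, stringsAsFactors = FALSE)
  sites$geometry <- I(lapply(seq_len(nrow(site_tab)), function(i) {
    rectset(site_tab$xmin[i], site_tab$ymin[i],
            site_tab$xmax[i], site_tab$ymax[i])
  }))

  ## ---- protected areas -------------------------------------------------
  set.seed(substream_seed(spec$seed, "pas"))
  pa_rows <- vector("list", spec$n_pas)
  for (i in seq_len(spec$n_pas)) {
    kind <- sample(c("full", "left", "right", "background"), 1,
                   prob = c(0.40, 0.15, 0.15, 0.30))
    if (kind != "background" && nrow(site_tab) > 0) {
      s <- sample.int(nrow(site_tab), 1)
      x0 <- site_tab$xmin[s]; x1 <- site_tab$xmax[s]
      y0 <- site_tab$ymin[s]; y1 <- site_tab$ymax[s]
      if (kind == "left") x1 <- (x0 + x1) / 2
      if (kind == "right") x0 <- (x0 + x1) / 2
    } else {
      cty <- sample.int(n, 1)
      marine <- stats::runif(1) < 0.25
      y_base <- if (marine) 0.5 else 0
      w <- stats::runif(1, 0.1, 0.4)
      h <- stats::runif(1, 0.1, 0.4)
      x0 <- (cty - 1) + stats::runif(1, 0, 1 - w); x1 <- x0 + w
      y0 <- y_base + stats::runif(1, 0, 0.5 - h); y1 <- y0 + h
    }
    cx <- (x0 + x1) / 2; cy <- (y0 + y1) / 2
    pa_rows[[i]] <- data.frame(
      pa_id = sprintf("pa%04d", i),
      country_code = iso[min(n, floor(cx) + 1)],
      realm = if (cy >= 0.5) "marine" else "terrestrial",
      year_established = sample(seq(spec$pa_year_range[1],
                                    spec$pa_year_range[2]), 1),
      xmin = x0, ymin = y0, xmax = x1, ymax = y1,
      stringsAsFactors = FALSE)
  }
  pa_tab <- if (spec$n_pas > 0) do.call(rbind, pa_rows) else
    data.frame(pa_id = character(), country_code = character(),
               realm = character(), year_established = numeric(),
               xmin = numeric(), ymin = numeric(), xmax = numeric(),
               ymax = numeric(), stringsAsFactors = FALSE)
  pas <- data.frame(pa_id = pa_tab$pa_id,
                    country_code = pa_tab$country_code,
                    realm = pa_tab$realm,
                    year_established = as.numeric(pa_tab$year_established),
                    stringsAsFactors = FALSE)
  pas$geometry <- I(lapply(seq_len(nrow(pa_tab)), function(i) {
    rectset(pa_tab$xmin[i], pa_tab$ymin[i], pa_tab$xmax[i], pa_tab$ymax[i])
  }))

  ## ---- mask establishment years ---------------------------------------
  masked <- mask_pa_years(pas, spec$undated_pa_fraction,
                          seed = substream_seed(spec$seed, "masking"))

  ## ---- ground truth by direct enumeration -----------------------------
  truth <- enumerate_truth(spec, schemes, species_id, group, category,
                           range_units, net_steps, fractions, sites,
                           masked$true_years, masked$pas, unit_geoms)

  list(spec = spec, schemes = schemes, assessments = assessments,
       occurrences = occurrences, changes = changes, fractions = fractions,
       period = spec$period, sites = sites, pas = masked$pas,
       unit_geoms = unit_geoms, truth = truth)
}

# truth is tabulated with plain nested loops over the generator's own
# bookkeeping (true ranges, true steps, true years), independently of the
# pipeline's filtering and aggregation code paths
enumerate_truth <- function(spec, schemes, species_id, group, category,
                            range_units, net_steps, fractions, sites,
                            true_years, pas, unit_geoms) {
  n_sp <- length(species_id)
  country_ranges <- lapply(range_units, function(u) setdiff(u, "ABNJ"))
  all_groups <- c(unique(group), "All")

  count_rows <- list()
  rli_rows <- list()
  for (sname in names(schemes)) {
    scheme <- schemes[[sname]]
    for (level in c("region", "subregion")) {
      fr <- fractions[[sname]][[level]]
      for (u in scheme_units(scheme, level, include_special = TRUE)) {
        members <- scheme_members(scheme, u, level)
        for (g in all_groups) {
          occ <- 0L; endemic <- 0L; v <- 0
          cat_occ <- stats::setNames(integer(length(.rl_categories)),
                                     .rl_categories)
          for (i in seq_len(n_sp)) {
            if (g != "All" && group[i] != g) next
            if (any(range_units[[i]] %in% members)) {
              occ <- occ + 1L
              cat_occ[category[i]] <- cat_occ[category[i]] + 1L
              if (u != "ABNJ" && all(country_ranges[[i]] %in% members)) {
                endemic <- endemic + 1L
              }
            }
            if (net_steps[i] != 0) {
              f <- fr$fraction[fr$species_id == species_id[i] &
                                 fr$unit == u]
              if (length(f) == 1) v <- v + net_steps[i] * f
            }
          }
          count_rows[[length(count_rows) + 1]] <- data.frame(
            scheme = sname, unit = u, level = level, group = g,
            n_occurring = occ, n_endemic = endemic,
            as.list(cat_occ), stringsAsFactors = FALSE)
          rli_rows[[length(rli_rows) + 1]] <- data.frame(
            scheme = sname, unit = u, level = level, group = g,
            value = v / spec$period$years, stringsAsFactors = FALSE)
        }
      }
    }
  }
  counts <- do.call(rbind, count_rows)
  rli <- do.call(rbind, rli_rows)
  rownames(counts) <- NULL
  rownames(rli) <- NULL

  # geometric truths use the exact engine on the raw rectangles
  site_cov <- list(); pa_cov <- list()
  for (sname in names(schemes)) {
    for (level in c("region", "subregion")) {
      for (tp in c("IBA", "AZE")) {
        sc <- site_coverage(sites, unit_geoms[[sname]][[level]], tp)
        sc$level <- level
        sc$scheme <- sname
        site_cov[[length(site_cov) + 1]] <- sc
      }
      pc <- pa_coverage(pas, unit_geoms[[sname]][[level]])
      pc$level <- level
      pc$scheme <- sname
      pa_cov[[length(pa_cov) + 1]] <- pc
    }
  }

  # true (pre-mask) trend series per site type, over all sites
  trend_years <- seq(spec$pa_year_range[1], spec$pa_year_range[2] + 5)
  pas_true <- pas
  pas_true$year_established <- as.numeric(true_years[pas$pa_id])
  trend <- lapply(stats::setNames(c("IBA", "AZE"), c("IBA", "AZE")),
                  function(tp) {
    st <- sites[sites$site_type == tp, , drop = FALSE]
    list(years = trend_years,
         pct = coverage_series(st, pas_true, trend_years))
  })

  list(counts = counts, rli = rli,
       site_coverage = do.call(rbind, site_cov),
       pa_coverage = do.call(rbind, pa_cov),
       true_years = true_years,
       trend_years = trend_years,
       trend = trend)
}
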