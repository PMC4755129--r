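#' Species tabulation: occurrence, endemism, category counts, threat bounds
#'
#' Species are tabulated against a region scheme from country-coded
#' occurrence records. A species *occurs* in a unit if it has at least one
#' occurrence record -- after excluding vagrant, uncertain-origin and
#' introduced records -- in one of the unit's member countries (or in the
#' special unit itself, e.g. ABNJ). A species is *endemic* to a unit if,
#' after the same filtering, it is not recorded from any country outside
#' the unit. The threatened fraction of a species set is reported as three
#' percentages bracketing the unknown status of Data Deficient (DD) species.
#'
#' @name species_metrics
#' @keywords internal
NULL

.rl_categories <- c("EX", "EW", "CR", "EN", "VU", "NT", "LC", "DD", "NE")
.threatened_categories <- c("CR", "EN", "VU")
# occurrence origins that never count towards occurrence or endemism
.excluded_origins <- c("vagrant", "uncertain", "introduced")

#' Normalize occurrence origin codes
#'
#' Maps common source spellings onto the canonical vocabulary
#' `native`, `reintroduced`, `vagrant`, `uncertain`, `introduced`.
#' Reintroduced populations count as native. Unknown tokens default to
#' `"native"` with a warning, since only the three excluded classes change
#' any result.
#'
#' @param origin character vector of raw origin codes.
#' @return character vector in the canonical vocabulary.
#' @export
normalize_origin <- function(origin) {
  key <- tolower(trimws(as.character(origin)))
  alias <- c(
    "native" = "native",
    "reintroduced" = "native",
    "vagrant" = "vagrant",
    "uncertain" = "uncertain",
    "origin uncertain" = "uncertain",
    "presence uncertain" = "uncertain",
    "introduced" = "introduced"
  )
  out <- unname(alias[key])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unknown origin code(s) treated as native: ",
            paste(unique(origin[unknown]), collapse = ", "), call. = FALSE)
    out[unknown] <- "native"
  }
  out
}

# occurrence records that count: drop vagrant / uncertain / introduced
filter_occurrences <- function(occurrences) {
  stopifnot(is.data.frame(occurrences))
  if (nrow(occurrences) == 0) {
    return(data.frame(species_id = character(), unit_code = character(),
                      stringsAsFactors = FALSE))
  }
  required <- c("species_id", "unit_code", "origin")
  missing_cols <- setdiff(required, names(occurrences))
  if (length(missing_cols) > 0) {
    stop("occurrence table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ori <- normalize_origin(occurrences$origin)
  keep <- !(ori %in% .excluded_origins)
  data.frame(species_id = as.character(occurrences$species_id)[keep],
             unit_code = trimws(as.character(occurrences$unit_code))[keep],
             stringsAsFactors = FALSE)
}

#' Species occurring in a unit
#'
#' @param occurrences data frame with columns `species_id`, `unit_code`
#'   (ISO3 or special unit label) and `origin`.
#' @param scheme a [region_scheme()].
#' @param unit unit label.
#' @param level `"region"` or `"subregion"`.
#' @return character vector of species ids (sorted, unique).
#' @export
species_occurring <- function(occurrences, scheme, unit,
                              level = c("region", "subregion")) {
  level <- match_level(level)
  members <- scheme_members(scheme, unit, level)
  occ <- filter_occurrences(occurrences)
  sort(unique(occ$species_id[occ$unit_code %in% members]))
}

#' Species endemic to a unit
#'
#' A species is endemic if none of its (filtered) country records fall
#' outside the unit. Records against special units (e.g. ABNJ) are not
#' country records and do not break endemism to a country-based unit.
#' Endemism *to* a special unit itself is rejected with a warning: no species
#' is expected to occur only on the high seas, and the notion is not
#' meaningful for the Excluded unit.
#'
#' @inheritParams species_occurring
#' @return character vector of species ids (sorted, unique).
#' @export
species_endemic <- function(occurrences, scheme, unit,
                            level = c("region", "subregion")) {
  level <- match_level(level)
  if (is_special_unit(scheme, unit)) {
    warning("endemism to special unit '", unit,
            "' is not defined; returning empty set", call. = FALSE)
    return(character())
  }
  members <- scheme_members(scheme, unit, level)
  occ <- filter_occurrences(occurrences)
  inside <- unique(occ$species_id[occ$unit_code %in% members])
  # country records only; special-unit records are ignored for endemism
  country_occ <- occ[!occ$unit_code %in% scheme$special_units, , drop = FALSE]
  outside <- unique(country_occ$species_id[
    !country_occ$unit_code %in% members])
  sort(setdiff(inside, outside))
}

#' Count Red List categories over a species set
#'
#' @param species_ids character vector of species ids.
#' @param assessments data frame with columns `species_id`, `category` and
#'   optionally `group`, `flag`.
#' @return named integer vector over the nine categories plus
#'   `total_assessed` (all categories except NE).
#' @export
category_counts <- function(species_ids, assessments) {
  stopifnot(is.data.frame(assessments))
  species_ids <- unique(as.character(species_ids))
  counts <- stats::setNames(integer(length(.rl_categories)), .rl_categories)
  if (length(species_ids) > 0) {
    i <- match(species_ids, as.character(assessments$species_id))
    if (anyNA(i)) {
      stop("species without assessment: ",
           paste(species_ids[is.na(i)], collapse = ", "), call. = FALSE)
    }
    cat <- toupper(trimws(as.character(assessments$category)[i]))
    bad <- !cat %in% .rl_categories
    if (any(bad)) {
      stop("unknown Red List category: ",
           paste(unique(cat[bad]), collapse = ", "), call. = FALSE)
    }
    tab <- table(factor(cat, levels = .rl_categories))
    counts[] <- as.integer(tab)
  }
  c(counts, total_assessed = sum(counts[setdiff(.rl_categories, "NE")]))
}

#' Threatened-percentage bounds under Data Deficiency
#'
#' The proportion threatened (CR+EN+VU) among extant assessed species is
#' uncertain because Data Deficient species may or may not be threatened.
#' Three percentages bracket it:
#' \describe{
#'   \item{lower}{all DD assumed not threatened:
#'     100 (CR+EN+VU) / (total assessed - EX)}
#'   \item{best}{DD assumed threatened in the same proportion as
#'     data-sufficient species:
#'     100 (CR+EN+VU) / (total assessed - EX - DD)}
#'   \item{upper}{all DD assumed threatened:
#'     100 (CR+EN+VU+DD) / (total assessed - EX)}
#' }
#' Extinct in the Wild (EW) species remain in every denominator; only EX is
#' subtracted. Not Evaluated species are outside `total_assessed` entirely.
#' A zero denominator yields `NA` (not applicable), never an error.
#'
#' @param counts named vector as returned by [category_counts()] (the
#'   `total_assessed` element is recomputed if absent).
#' @return named numeric vector `c(pct_lower, pct_best, pct_upper)` in
#'   percent.
#' @export
threat_bounds <- function(counts) {
  get <- function(nm) if (nm %in% names(counts)) as.numeric(counts[[nm]]) else 0
  total <- if ("total_assessed" %in% names(counts)) {
    as.numeric(counts[["total_assessed"]])
  } else {
    sum(vapply(setdiff(.rl_categories, "NE"), get, numeric(1)))
  }
  thr <- get("CR") + get("EN") + get("VU")
  ex <- get("EX")
  dd <- get("DD")
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(pct_lower = pct(thr, total - ex),
    pct_best = pct(thr, total - ex - dd),
    pct_upper = pct(thr + dd, total - ex))
}

#' Tabulate species metrics per unit and taxonomic group
#'
#' Builds the per-unit species table: one row per unit x taxonomic group,
#' plus an all-groups row per unit, carrying Red List category counts and
#' the three threatened-percentage bounds. `mode = "occurring"` counts
#' species occurring in each unit; `mode = "endemic"` counts species endemic
#' to it (special units are skipped in endemic mode).
#'
#' @inheritParams species_occurring
#' @param assessments data frame with columns `species_id`, `group`,
#'   `category` (and optionally `flag`).
#' @param mode `"occurring"` or `"endemic"`.
#' @param level `"region"`, `"subregion"` or `"both"`.
#' @param all_groups_label label of the pooled row (default `"All"`).
#' @return data frame with columns `unit`, `level`, `group`, one column per
#'   Red List category, `total_assessed`, `pct_lower`, `pct_best`,
#'   `pct_upper`.
#' @export
tabulate_units <- function(scheme, assessments, occurrences,
                           mode = c("occurring", "endemic"),
                           level = c("both", "region", "subregion"),
                           all_groups_label = "All") {
  mode <- match.arg(mode)
  level <- match.arg(level)
  levels_wanted <- if (level == "both") .unit_levels else level
  assessments$species_id <- as.character(assessments$species_id)
  groups <- unique(as.character(assessments$group))
  rows <- list()
  for (lv in levels_wanted) {
    include_special <- (mode == "occurring")
    for (u in scheme_units(scheme, lv, include_special = include_special)) {
      if (lv == "subregion" && is_special_unit(scheme, u)) next
      sp <- if (mode == "occurring") {
        species_occurring(occurrences, scheme, u, lv)
      } else {
        species_endemic(occurrences, scheme, u, lv)
      }
      for (g in c(groups, all_groups_label)) {
        sp_g <- if (g == all_groups_label) sp else {
          intersect(sp, assessments$species_id[assessments$group == g])
        }
        cc <- category_counts(sp_g, assessments)
        tb <- threat_bounds(cc)
        rows[[length(rows) + 1]] <- data.frame(
          unit = u, level = lv, group = g,
          as.list(cc), as.list(tb),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(unit = character(), level = character(),
                      group = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
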