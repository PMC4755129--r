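#' Spatial downscaling of Red List Index change
#'
#' The Red List Index (RLI) tracks aggregate change in extinction risk for a
#' comprehensively assessed taxon. Its trend is driven only by *genuine*
#' category changes -- those caused by real improvement or deterioration, not
#' by revised knowledge or taxonomy. The global annual net change can be
#' apportioned to spatial units: each species' signed category changes are
#' weighted by the fraction of the species' range falling in each unit, and
#' the weighted sum is divided by the assessment period length in years.
#' Because range fractions sum to one over the units of a level, the unit
#' contributions sum exactly to the global annual net change.
#'
#' @name rli_downscaling
#' @keywords internal
NULL

# ranked categories for index purposes; DD and NE have no rank
.rank_map <- c(LC = 0, NT = 1, VU = 2, EN = 3, CR = 4, EW = 5, EX = 5)

#' Ordinal rank of a Red List category on the index scale
#'
#' The scale runs, in order of increasing extinction risk:
#' LC (0), NT (1), VU (2), EN (3), CR (4), then EW and EX jointly at 5.
#' A CR assessment flagged Possibly Extinct (PE) or Possibly Extinct in the
#' Wild (PEW) is ranked with EW/EX at 5. DD and NE are not rankable.
#'
#' @param category character vector of categories.
#' @param flag character vector, `"none"`, `"PE"` or `"PEW"` (recycled).
#' @return integer vector of ranks.
#' @export
category_rank <- function(category, flag = "none") {
  category <- toupper(trimws(as.character(category)))
  flag <- toupper(trimws(as.character(flag)))
  flag[flag == "" | is.na(flag)] <- "NONE"
  n <- max(length(category), length(flag))
  category <- rep_len(category, n)
  flag <- rep_len(flag, n)
  bad_flag <- flag %in% c("PE", "PEW") & category != "CR"
  if (any(bad_flag)) {
    stop("PE/PEW flags are only valid on CR assessments", call. = FALSE)
  }
  r <- unname(.rank_map[category])
  if (anyNA(r)) {
    stop("category not rankable on the index scale: ",
         paste(unique(category[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  r[flag %in% c("PE", "PEW")] <- 5L
  as.integer(r)
}

#' Decompose a recorded category pair into unit-step change events
#'
#' A genuine change from `cat_start` to `cat_end` is decomposed into one
#' event per category step: each step of increasing extinction risk scores
#' -1, each step of decreasing risk scores +1. Non-genuine pairs produce no
#' events.
#'
#' @param cat_start,cat_end start and end categories (both rankable).
#' @param genuine logical; was the change a genuine change in risk?
#' @param flag_start,flag_end PE/PEW flags accompanying CR categories.
#' @return data frame with columns `step` (one row per unit step; zero rows
#'   when nothing changed or the change is not genuine).
#' @export
events_from_category_pair <- function(cat_start, cat_end, genuine = TRUE,
                                      flag_start = "none",
                                      flag_end = "none") {
  if (!isTRUE(genuine)) {
    return(data.frame(step = integer()))
  }
  r0 <- category_rank(cat_start, flag_start)
  r1 <- category_rank(cat_end, flag_end)
  d <- r1 - r0
  if (d == 0) return(data.frame(step = integer()))
  # risk increase (rank up) scores -1 per category step
  data.frame(step = rep.int(-sign(d), abs(d)))
}

#' Build a per-species step table from recorded category changes
#'
#' Accepts a table of recorded assessment-to-assessment changes
#' (`species_id`, `cat_start`, `cat_end`, `genuine`, optionally
#' `flag_start`, `flag_end`) and decomposes each row into unit steps.
#' Rows whose endpoints are not rankable (DD or NE on either side) are
#' dropped with a warning rather than an error: such changes cannot enter
#' the index.
#'
#' @param changes data frame of recorded changes.
#' @return data frame with columns `species_id`, `step` (one row per unit
#'   step).
#' @export
decompose_changes <- function(changes) {
  stopifnot(is.data.frame(changes))
  n <- nrow(changes)
  if (n == 0) {
    return(data.frame(species_id = character(), step = integer(),
                      stringsAsFactors = FALSE))
  }
  fs <- if ("flag_start" %in% names(changes)) changes$flag_start else "none"
  fe <- if ("flag_end" %in% names(changes)) changes$flag_end else "none"
  fs <- rep_len(as.character(fs), n)
  fe <- rep_len(as.character(fe), n)
  out <- vector("list", n)
  dropped <- character()
  for (i in seq_len(n)) {
    ev <- tryCatch(
      events_from_category_pair(changes$cat_start[i], changes$cat_end[i],
                                isTRUE(as.logical(changes$genuine[i])),
                                fs[i], fe[i]),
      error = function(e) NULL)
    if (is.null(ev)) {
      dropped <- c(dropped, as.character(changes$species_id[i]))
      next
    }
    if (nrow(ev) > 0) {
      out[[i]] <- data.frame(species_id = as.character(changes$species_id[i]),
                             step = ev$step, stringsAsFactors = FALSE)
    }
  }
  if (length(dropped) > 0) {
    warning("dropped change(s) with unrankable endpoints for species: ",
            paste(unique(dropped), collapse = ", "), call. = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(species_id = character(), step = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Define an assessment period
#' @param start_year,end_year calendar years, `end_year > start_year`.
#' @return object of class `assessment_period` with a `years` span.
#' @export
assessment_period <- function(start_year, end_year) {
  start_year <- as.numeric(start_year)
  end_year <- as.numeric(end_year)
  if (!(end_year > start_year)) {
    stop("assessment period must have positive span", call. = FALSE)
  }
  structure(list(start_year = start_year, end_year = end_year,
                 years = end_year - start_year),
            class = "assessment_period")
}

period_years <- function(period) {
  if (inherits(period, "assessment_period")) return(period$years)
  y <- as.numeric(period)
  if (length(y) != 1 || !is.finite(y) || y <= 0) {
    stop("period must be an assessment_period or a positive number of years",
         call. = FALSE)
  }
  y
}

#' Validate a range-fraction table
#'
#' Per species, range fractions over the units of one level (including any
#' special units such as ABNJ) must sum to 1 within `tol`. Violations raise
#' an error; fractions are never silently renormalized.
#'
#' @param fractions data frame with columns `species_id`, `unit`, `fraction`.
#' @param tol absolute tolerance on the per-species sum (default `1e-6`).
#' @param species optional subset of species ids to check.
#' @return invisibly `TRUE`.
#' @export
validate_fractions <- function(fractions, tol = 1e-6, species = NULL) {
  stopifnot(is.data.frame(fractions))
  f <- fractions
  f$species_id <- as.character(f$species_id)
  if (!is.null(species)) f <- f[f$species_id %in% species, , drop = FALSE]
  if (nrow(f) == 0) return(invisible(TRUE))
  if (any(f$fraction < 0 | f$fraction > 1)) {
    stop("range fractions must lie in [0, 1]", call. = FALSE)
  }
  sums <- tapply(f$fraction, f$species_id, sum)
  bad <- names(sums)[abs(sums - 1) > tol]
  if (length(bad) > 0) {
    stop("range fractions do not sum to 1 for species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Weighted annual contribution of each unit to global RLI change
#'
#' For each unit u, the contribution is
#' `sum over species s of net_steps(s) * fraction(s, u), divided by the
#' period length in years`. Negative values indicate net deterioration
#' concentrated in that unit.
#'
#' @param events data frame with columns `species_id`, `step` (see
#'   [decompose_changes()]).
#' @param fractions range-fraction table for the requested level, columns
#'   `species_id`, `unit`, `fraction`.
#' @param period an [assessment_period()] or a number of years.
#' @param scheme optional [region_scheme()]; when given, every unit of
#'   `level` appears in the output (zero-filled) and fraction units are
#'   checked against the scheme.
#' @param level `"region"` or `"subregion"` (used with `scheme`).
#' @return data frame with columns `unit`, `value`.
#' @export
weighted_annual_change <- function(events, fractions, period,
                                   scheme = NULL,
                                   level = c("region", "subregion")) {
  level <- match_level(level)
  years <- period_years(period)
  stopifnot(is.data.frame(events), is.data.frame(fractions))
  events$species_id <- as.character(events$species_id)
  fractions$species_id <- as.character(fractions$species_id)
  fractions$unit <- trimws(as.character(fractions$unit))

  sp_events <- unique(events$species_id)
  missing_w <- setdiff(sp_events, fractions$species_id)
  if (length(missing_w) > 0) {
    stop("species with change events but no range fractions: ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  }
  validate_fractions(fractions, species = sp_events)

  units_out <- if (!is.null(scheme)) {
    scheme_units(scheme, level, include_special = TRUE)
  } else {
    unique(fractions$unit)
  }
  value <- stats::setNames(numeric(length(units_out)), units_out)
  if (length(sp_events) > 0) {
    net <- tapply(events$step, events$species_id, sum)
    fr <- fractions[fractions$species_id %in% sp_events, , drop = FALSE]
    unknown_units <- setdiff(unique(fr$unit), units_out)
    if (length(unknown_units) > 0) {
      stop("range-fraction unit(s) not in scheme: ",
           paste(unknown_units, collapse = ", "), call. = FALSE)
    }
    contrib <- fr$fraction * as.numeric(net[fr$species_id]) / years
    agg <- tapply(contrib, fr$unit, sum)
    value[names(agg)] <- as.numeric(agg)
  }
  data.frame(unit = units_out, value = as.numeric(value),
             stringsAsFactors = FALSE)
}

#' Residual of the global decomposition identity
#'
#' With per-species fractions summing to 1, the unit contributions must sum
#' to the global net change divided by the period length. Returns
#' `sum(contributions$value) - sum(net steps)/years`; an absolute value
#' above ~1e-9 indicates unnormalized fractions or a computation fault.
#'
#' @param contributions output of [weighted_annual_change()].
#' @param events the step table the contributions were computed from.
#' @param period the same period.
#' @return numeric residual.
#' @export
additivity_check <- function(contributions, events, period) {
  years <- period_years(period)
  global <- if (nrow(events) > 0) sum(events$step) / years else 0
  sum(contributions$value) - global
}

#' Downscaled RLI contributions per taxon
#'
#' Convenience wrapper: decomposes recorded changes per taxonomic group and
#' stacks [weighted_annual_change()] results into one table shaped like the
#' published regional RLI files.
#'
#' @param changes recorded change table with a `group` column (see
#'   [decompose_changes()]).
#' @param fractions range-fraction table for `level`.
#' @param period an [assessment_period()] or number of years (single period
#'   applied to all groups, or a named list per group).
#' @param scheme a [region_scheme()].
#' @param level `"region"` or `"subregion"`.
#' @return data frame with columns `unit`, `level`, `group`,
#'   `weighted_annual_change`.
#' @export
rli_contributions <- function(changes, fractions, period, scheme,
                              level = c("region", "subregion")) {
  level <- match_level(level)
  groups <- unique(as.character(changes$group))
  rows <- list()
  for (g in groups) {
    per <- if (is.list(period) && !inherits(period, "assessment_period")) {
      period[[g]]
    } else {
      period
    }
    ev <- decompose_changes(changes[changes$group == g, , drop = FALSE])
    w <- weighted_annual_change(ev, fractions, per, scheme, level)
    rows[[length(rows) + 1]] <- data.frame(
      unit = w$unit, level = level, group = g,
      weighted_annual_change = w$value, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(unit = character(), level = character(),
                      group = character(),
                      weighted_annual_change = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
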