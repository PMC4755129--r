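#' Region schemes: country-to-region/subregion mappings
#'
#' A region scheme maps ISO3 country codes to a region and a subregion under a
#' named regionalization (for example the GEO or IPBES schemes used by
#' intergovernmental environmental assessments). Subregions partition regions:
#' every subregion belongs to exactly one region. A scheme may additionally
#' carry *special units* -- spatial units that are not countries, such as
#' "ABNJ" (Areas Beyond National Jurisdiction, the high seas) or "Excluded"
#' (the Antarctic). Special units act as their own region and subregion and
#' have no ISO3 code.
#'
#' @name region_scheme
#' @keywords internal
NULL

.unit_levels <- c("region", "subregion")

match_level <- function(level) {
  match.arg(level, .unit_levels)
}

#' Construct a region scheme from a table of country rows
#'
#' Validates and assembles a `region_scheme` object. Labels are compared after
#' trimming surrounding whitespace; case is preserved verbatim. Unit ordering
#' is first appearance in the input rows, with special units last.
#'
#' @param entries data frame with columns `iso3`, `region`, `subregion` and
#'   optionally `country_name`. ISO3 codes must be unique three-letter
#'   uppercase tokens.
#' @param scheme_name single string naming the scheme (e.g. `"GEO"`).
#' @param special_units character vector of non-country unit labels (e.g.
#'   `"ABNJ"`); may be empty.
#' @return an object of class `region_scheme`.
#' @examples
#' s <- region_scheme(
#'   data.frame(iso3 = c("AFG", "ALB"),
#'              region = c("Asia+Pacific", "Europe"),
#'              subregion = c("South Asia", "Central Europe")),
#'   scheme_name = "demo")
#' unit_of(s, "AFG", "region")
#' @export
region_scheme <- function(entries, scheme_name = "scheme",
                          special_units = character()) {
  stopifnot(is.data.frame(entries))
  required <- c("iso3", "region", "subregion")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    stop("scheme table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trim <- function(x) trimws(as.character(x))
  entries <- data.frame(
    country_name = if ("country_name" %in% names(entries))
      trim(entries$country_name) else trim(entries$iso3),
    iso3 = trim(entries$iso3),
    region = trim(entries$region),
    subregion = trim(entries$subregion),
    stringsAsFactors = FALSE
  )
  special_units <- unique(trimws(as.character(special_units)))

  if (nrow(entries) > 0) {
    bad <- !grepl("^[A-Z]{3}$", entries$iso3)
    if (any(bad)) {
      stop("ISO3 codes must be 3-letter uppercase: ",
           paste(unique(entries$iso3[bad]), collapse = ", "), call. = FALSE)
    }
    dup <- unique(entries$iso3[duplicated(entries$iso3)])
    if (length(dup) > 0) {
      stop("duplicate ISO3 code(s) in scheme: ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
    # each subregion must nest in exactly one region
    sub_map <- unique(entries[, c("subregion", "region")])
    dup_sub <- unique(sub_map$subregion[duplicated(sub_map$subregion)])
    if (length(dup_sub) > 0) {
      stop("subregion(s) assigned to more than one region: ",
           paste(dup_sub, collapse = ", "), call. = FALSE)
    }
    if (any(entries$iso3 %in% special_units)) {
      stop("special units must not carry ISO3 codes", call. = FALSE)
    }
  }

  structure(
    list(scheme_name = as.character(scheme_name)[1],
         entries = entries,
         special_units = special_units),
    class = "region_scheme"
  )
}

#' Load a region scheme from a delimited file
#'
#' Reads a CSV with columns `country_name`, `iso3`, `region`, `subregion`
#' (extra columns are ignored) and validates it into a [region_scheme()].
#'
#' @param path path to the CSV file, or a data frame already in that shape.
#' @inheritParams region_scheme
#' @return a `region_scheme`.
#' @export
load_scheme <- function(path, scheme_name = NULL, special_units = character()) {
  if (is.data.frame(path)) {
    tab <- path
    if (is.null(scheme_name)) scheme_name <- "scheme"
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
    if (is.null(scheme_name)) {
      scheme_name <- sub("\\.csv$", "", basename(path))
    }
  }
  region_scheme(tab, scheme_name = scheme_name, special_units = special_units)
}

#' Load one of the packaged regionalizations
#'
#' Two regionalization tables ship with the package, transcribing the GEO and
#' IPBES country-to-region assignments used by the corresponding assessment
#' processes. Both get "ABNJ" as a special unit; IPBES additionally gets
#' "Excluded" (the Antarctic).
#'
#' @param name `"GEO"` or `"IPBES"`.
#' @return a `region_scheme`.
#' @export
builtin_scheme <- function(name = c("GEO", "IPBES")) {
  name <- match.arg(name)
  path <- system.file("extdata",
                      paste0("regionalization_", name, ".csv"),
                      package = "rlregions", mustWork = TRUE)
  special <- if (name == "IPBES") c("ABNJ", "Excluded") else "ABNJ"
  load_scheme(path, scheme_name = name, special_units = special)
}

#' Look up the region or subregion of a country
#'
#' @param scheme a `region_scheme`.
#' @param code ISO3 country code, or a special unit label.
#' @param level `"region"` or `"subregion"`.
#' @return the unit label (for a special unit, the label itself at either
#'   level).
#' @export
unit_of <- function(scheme, code, level = c("region", "subregion")) {
  stopifnot(inherits(scheme, "region_scheme"))
  level <- match_level(level)
  code <- trimws(code)
  if (code %in% scheme$special_units) return(code)
  i <- match(code, scheme$entries$iso3)
  if (is.na(i)) {
    stop("code not in scheme '", scheme$scheme_name, "': ", code,
         call. = FALSE)
  }
  scheme$entries[[level]][i]
}

#' List the units of a scheme at one level
#'
#' Units are returned in first-appearance order of the source table, with
#' special units appended last (in the order they were declared).
#'
#' @inheritParams unit_of
#' @param include_special append the scheme's special units?
#' @return character vector of unit labels.
#' @export
scheme_units <- function(scheme, level = c("region", "subregion"),
                         include_special = FALSE) {
  stopifnot(inherits(scheme, "region_scheme"))
  level <- match_level(level)
  u <- unique(scheme$entries[[level]])
  if (include_special) u <- c(u, scheme$special_units)
  u
}

#' Member country codes of one unit
#'
#' For a special unit the "member" is the unit label itself, so that
#' occurrence records coded directly against the unit (e.g. ABNJ) resolve.
#'
#' @inheritParams unit_of
#' @param unit unit label at `level`.
#' @return character vector of ISO3 codes (or the special label).
#' @export
scheme_members <- function(scheme, unit, level = c("region", "subregion")) {
  stopifnot(inherits(scheme, "region_scheme"))
  level <- match_level(level)
  unit <- trimws(unit)
  if (unit %in% scheme$special_units) return(unit)
  if (!unit %in% scheme$entries[[level]]) {
    stop("unit not in scheme '", scheme$scheme_name, "' at level ", level,
         ": ", unit, call. = FALSE)
  }
  scheme$entries$iso3[scheme$entries[[level]] == unit]
}

#' Parent region of a subregion
#' @inheritParams scheme_members
#' @param subregion subregion label.
#' @return region label.
#' @export
parent_region <- function(scheme, subregion) {
  stopifnot(inherits(scheme, "region_scheme"))
  subregion <- trimws(subregion)
  if (subregion %in% scheme$special_units) return(subregion)
  i <- match(subregion, scheme$entries$subregion)
  if (is.na(i)) stop("unknown subregion: ", subregion, call. = FALSE)
  scheme$entries$region[i]
}

#' Is a unit one of the scheme's special (non-country) units?
#' @inheritParams scheme_members
#' @return logical.
#' @export
is_special_unit <- function(scheme, unit) {
  trimws(unit) %in% scheme$special_units
}

#' Summarize a scheme as one row per unit
#'
#' @inheritParams unit_of
#' @return data frame with columns `unit`, `level`, `n_countries` covering
#'   both levels plus special units (which count zero countries).
#' @export
scheme_summary <- function(scheme) {
  stopifnot(inherits(scheme, "region_scheme"))
  rows <- list()
  for (level in .unit_levels) {
    for (u in scheme_units(scheme, level)) {
      rows[[length(rows) + 1]] <- data.frame(
        unit = u, level = level,
        n_countries = length(scheme_members(scheme, u, level)),
        stringsAsFactors = FALSE)
    }
  }
  for (u in scheme$special_units) {
    rows[[length(rows) + 1]] <- data.frame(
      unit = u, level = "region", n_countries = 0L, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
as.data.frame.region_scheme <- function(x, ...) {
  x$entries
}

#' @export
print.region_scheme <- function(x, ...) {
  cat("Region scheme '", x$scheme_name, "': ", nrow(x$entries),
      " countries, ", length(scheme_units(x, "region")), " regions, ",
      length(scheme_units(x, "subregion")), " subregions",
      if (length(x$special_units) > 0)
        paste0(" (+ ", paste(x$special_units, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}
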