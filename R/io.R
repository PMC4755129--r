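#' Interchange files and pipeline products
#'
#' Tabular inputs are plain CSVs; geometric layers are GeoJSON. Every
#' product CSV starts with one `#`-prefixed metadata line (tool version,
#' seed, threshold) followed by an ordinary header row, so files are
#' self-describing yet trivially machine-readable. Percentages are
#' serialized to one decimal; counts as integers; not-applicable values as
#' empty fields. Output files follow the `<Product>_<SCHEME>.csv` naming
#' convention of the published regional data deposits
#' (`Total_Species_*`, `Endemic_Species_*`, `Red_List_Index_*`,
#' `IBAs_AZEs_*`, `PAs_*`, `Protected_IBAs_*`, `Protected_AZEs_*`).
#'
#' @name io
#' @keywords internal
NULL

pkg_version <- function() {
  as.character(utils::packageVersion("rlregions"))
}

meta_line <- function(seed = NA, threshold = NA) {
  paste0("# rlregions ", pkg_version(),
         " seed=", ifelse(is.na(seed), "NA", format(seed)),
         " threshold=", ifelse(is.na(threshold), "NA", format(threshold)))
}

# serialize a data frame with per-column formatting rules
format_product <- function(df) {
  out <- df
  for (nm in names(out)) {
    v <- out[[nm]]
    if (grepl("^pct_|_pct$|^median_pct$|^ci_", nm) && is.numeric(v)) {
      out[[nm]] <- ifelse(is.na(v), "", sprintf("%.1f", v))
    } else if (nm %in% c("mean_size_km2", "weighted_annual_change",
                         "value") && is.numeric(v)) {
      out[[nm]] <- ifelse(is.na(v), "", sprintf("%.6g", v))
    } else if (is.numeric(v)) {
      out[[nm]] <- ifelse(is.na(v), "", format(v, scientific = FALSE,
                                               trim = TRUE))
    } else {
      out[[nm]] <- ifelse(is.na(v), "", as.character(v))
    }
  }
  out
}

#' Write one product CSV
#'
#' @param df product table.
#' @param path output path.
#' @param seed,threshold recorded in the metadata comment line.
#' @return invisibly `path`.
#' @export
write_product <- function(df, path, seed = NA, threshold = NA) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(meta_line(seed, threshold), con, sep = "\n")
  utils::write.table(format_product(df), con, sep = ",", quote = TRUE,
                     row.names = FALSE, qmethod = "double", eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a product CSV written by [write_product()]
#' @param path path to the file.
#' @return data frame (metadata line skipped).
#' @export
read_product <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

## ---- world bundle on disk ----------------------------------------------

#' Write a synthetic world bundle to a directory
#'
#' Writes every pipeline input in its interchange dialect: one
#' regionalization CSV per scheme, assessments/occurrences/changes CSVs,
#' range-fraction CSVs per scheme and level, GeoJSON layers for sites,
#' protected areas and unit land/sea geometries, and a `manifest.json`
#' recording the spec, seed and file paths. Ground truth is saved as
#' `truth.json` so downstream checks do not need to regenerate.
#'
#' @param world output of [generate_world()].
#' @param dir target directory (created if needed).
#' @return invisibly `dir`.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  wcsv <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "")
  }
  files <- list()
  for (nm in names(world$schemes)) {
    f <- paste0("regionalization_", nm, ".csv")
    wcsv(as.data.frame(world$schemes[[nm]]), p(f))
    files[[paste0("scheme_", nm)]] <- f
  }
  wcsv(world$assessments, p("assessments.csv"))
  wcsv(world$occurrences, p("occurrences.csv"))
  wcsv(world$changes, p("changes.csv"))
  files$assessments <- "assessments.csv"
  files$occurrences <- "occurrences.csv"
  files$changes <- "changes.csv"
  for (nm in names(world$fractions)) {
    for (level in c("region", "subregion")) {
      f <- paste0("range_fractions_", nm, "_", level, ".csv")
      wcsv(world$fractions[[nm]][[level]], p(f))
      files[[paste0("fractions_", nm, "_", level)]] <- f
    }
  }
  write_geojson_layer(world$sites, p("sites.geojson"))
  files$sites <- "sites.geojson"
  write_geojson_layer(world$pas, p("pas.geojson"))
  files$pas <- "pas.geojson"
  for (nm in names(world$unit_geoms)) {
    for (level in c("region", "subregion")) {
      f <- paste0("units_", nm, "_", level, ".geojson")
      write_unit_layer(world$unit_geoms[[nm]][[level]], p(f))
      files[[paste0("units_", nm, "_", level)]] <- f
    }
  }
  manifest <- list(
    tool = paste("rlregions", pkg_version()),
    seed = world$spec$seed,
    period = c(world$period$start_year, world$period$end_year),
    spec = world$spec[setdiff(names(world$spec), "period")],
    files = files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  truth <- world$truth
  truth$true_years <- as.list(truth$true_years)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

# unit land/sea geometries as a FeatureCollection with unit + part props
write_unit_layer <- function(unit_geoms, path) {
  rows <- list()
  for (i in seq_len(nrow(unit_geoms))) {
    for (part in c("land", "sea")) {
      g <- unit_geoms[[part]][[i]]
      if (rs_is_empty(g)) next
      rows[[length(rows) + 1]] <- data.frame(
        unit = unit_geoms$unit[i], part = part, stringsAsFactors = FALSE)
      rows[[length(rows)]]$geometry <- I(list(g))
    }
  }
  df <- do.call(rbind, rows)
  write_geojson_layer(df, path)
}

#' Read a unit land/sea GeoJSON layer
#' @param path layer written by the package (features carry `unit` and
#'   `part` attributes).
#' @return a [unit_geometry()] table.
#' @export
read_unit_layer <- function(path) {
  df <- read_geojson_layer(path)
  units <- unique(df$unit)
  pick <- function(u, part) {
    i <- which(df$unit == u & df$part == part)
    if (length(i) == 0) rectset() else dissolve(df$geometry[i])
  }
  unit_geometry(units,
                lapply(units, pick, part = "land"),
                lapply(units, pick, part = "sea"))
}

#' Read a world bundle from a directory
#'
#' Counterpart of [write_world()]: reads the manifest and reassembles the
#' pipeline input bundle. Input validation errors (missing files, missing
#' columns) are aggregated and reported together.
#'
#' @param dir directory containing `manifest.json`.
#' @return list shaped like the output of [generate_world()] (without
#'   `truth`, which is reloaded only if present).
#' @export
read_world <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    stop("no manifest.json in ", dir, call. = FALSE)
  }
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  p <- function(f) file.path(dir, f)
  problems <- character()
  need <- function(f) {
    if (!file.exists(p(f))) {
      problems <<- c(problems, paste0("missing file: ", f))
      FALSE
    } else TRUE
  }
  rcsv <- function(f, required_cols) {
    if (!need(f)) return(NULL)
    df <- utils::read.csv(p(f), stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    miss <- setdiff(required_cols, names(df))
    if (length(miss) > 0) {
      problems <<- c(problems, paste0(f, ": missing column(s) ",
                                      paste(miss, collapse = ", ")))
      return(NULL)
    }
    df
  }
  scheme_keys <- grep("^scheme_", names(man$files), value = TRUE)
  schemes <- list()
  for (k in scheme_keys) {
    nm <- sub("^scheme_", "", k)
    tab <- rcsv(man$files[[k]], c("iso3", "region", "subregion"))
    if (!is.null(tab)) {
      schemes[[nm]] <- region_scheme(tab, scheme_name = nm,
                                     special_units = "ABNJ")
    }
  }
  assessments <- rcsv(man$files$assessments,
                      c("species_id", "group", "category"))
  occurrences <- rcsv(man$files$occurrences,
                      c("species_id", "unit_code", "origin"))
  changes <- rcsv(man$files$changes,
                  c("species_id", "group", "cat_start", "cat_end",
                    "genuine"))
  fractions <- list()
  for (nm in names(schemes)) {
    fractions[[nm]] <- list()
    for (level in c("region", "subregion")) {
      fractions[[nm]][[level]] <- rcsv(
        man$files[[paste0("fractions_", nm, "_", level)]],
        c("species_id", "unit", "fraction"))
    }
  }
  sites <- if (need(man$files$sites)) {
    read_geojson_layer(p(man$files$sites))
  }
  pas <- if (need(man$files$pas)) {
    df <- read_geojson_layer(p(man$files$pas))
    if (!"year_established" %in% names(df)) {
      df$year_established <- NA_real_
    }
    df$year_established <- suppressWarnings(
      as.numeric(df$year_established))
    df
  }
  unit_geoms <- list()
  for (nm in names(schemes)) {
    unit_geoms[[nm]] <- list()
    for (level in c("region", "subregion")) {
      f <- man$files[[paste0("units_", nm, "_", level)]]
      if (need(f)) unit_geoms[[nm]][[level]] <- read_unit_layer(p(f))
    }
  }
  if (length(problems) > 0) {
    stop("input bundle validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  period <- assessment_period(man$period[1], man$period[2])
  truth <- NULL
  if (file.exists(p("truth.json"))) {
    truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
    truth$true_years <- unlist(truth$true_years)
  }
  list(schemes = schemes, assessments = assessments,
       occurrences = occurrences, changes = changes,
       fractions = fractions, period = period, sites = sites, pas = pas,
       unit_geoms = unit_geoms, truth = truth,
       seed = man$seed)
}

## ---- pipeline products --------------------------------------------------

# sites grouped by the unit containing their representative point;
# ABNJ and units holding no sites are dropped, as in the published trend
# tables
sites_by_unit <- function(sites, unit_geoms) {
  reps <- lapply(sites$geometry, rs_rep_point)
  assign <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(unit_geoms))) {
    total <- unit_total_geom(unit_geoms, i)
    hit <- vapply(reps, function(pt) {
      rs_contains_point(total, pt["x"], pt["y"])
    }, logical(1))
    assign[is.na(assign) & hit] <- unit_geoms$unit[i]
  }
  assign
}

#' Per-unit protection trend products
#'
#' Builds the trend table (`unit`, `level`, `year`, `median_pct`,
#' `ci_low`, `ci_high`) for one site type under one scheme level. Units
#' without sites of the type, and ABNJ, are omitted.
#'
#' @param sites,pas input layers.
#' @param unit_geoms a [unit_geometry()] table for the level.
#' @param site_type `"IBA"` or `"AZE"`.
#' @param level level label written into the table.
#' @param years year grid.
#' @param n_reps,threshold,seed passed to [trend_with_ci()].
#' @return data frame.
#' @export
pa_trend_table <- function(sites, pas, unit_geoms, site_type, level,
                           years, n_reps = 1000, threshold = 0.98,
                           seed = NULL) {
  sel <- sites[sites$site_type == site_type, , drop = FALSE]
  assign <- sites_by_unit(sel, unit_geoms)
  rows <- list()
  for (u in unit_geoms$unit) {
    if (u == "ABNJ") next
    st <- sel[!is.na(assign) & assign == u, , drop = FALSE]
    if (nrow(st) == 0) next
    tr <- trend_with_ci(st, pas, years, n_reps = n_reps,
                        threshold = threshold, seed = seed)
    rows[[length(rows) + 1]] <- data.frame(
      unit = u, level = level, year = tr$years,
      median_pct = tr$median_pct, ci_low = tr$ci_low,
      ci_high = tr$ci_high, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(unit = character(), level = character(),
                      year = numeric(), median_pct = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline and write every product file
#'
#' For each scheme in the bundle, writes the seven product CSVs:
#' `Total_Species_<S>.csv`, `Endemic_Species_<S>.csv`,
#' `Red_List_Index_<S>.csv`, `IBAs_AZEs_<S>.csv`, `PAs_<S>.csv`,
#' `Protected_IBAs_<S>.csv` and `Protected_AZEs_<S>.csv`. Outputs are
#' byte-identical across runs with the same inputs, options and seed.
#'
#' @param bundle a world bundle ([generate_world()] or [read_world()]).
#' @param out_dir output directory (created if needed).
#' @param n_reps Monte Carlo replicates for the trend products.
#' @param threshold whole-coverage threshold in (0, 1].
#' @param seed seed for the trend imputation draws.
#' @param years year grid for the trend products (default: from the
#'   earliest dated year to the latest dated year plus five).
#' @return invisibly a character vector of the files written.
#' @export
run_all <- function(bundle, out_dir, n_reps = 1000, threshold = 0.98,
                    seed = 1L, years = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(years)) {
    yr <- range(bundle$pas$year_established, na.rm = TRUE)
    years <- seq(yr[1], yr[2] + 5)
  }
  written <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_product(df, path, seed = seed, threshold = threshold)
    written <<- c(written, path)
  }
  for (nm in names(bundle$schemes)) {
    scheme <- bundle$schemes[[nm]]
    emit(tabulate_units(scheme, bundle$assessments, bundle$occurrences,
                        mode = "occurring"),
         paste0("Total_Species_", nm, ".csv"))
    emit(tabulate_units(scheme, bundle$assessments, bundle$occurrences,
                        mode = "endemic"),
         paste0("Endemic_Species_", nm, ".csv"))
    rli <- rbind(
      rli_contributions(bundle$changes, bundle$fractions[[nm]]$region,
                        bundle$period, scheme, "region"),
      rli_contributions(bundle$changes, bundle$fractions[[nm]]$subregion,
                        bundle$period, scheme, "subregion"))
    emit(rli, paste0("Red_List_Index_", nm, ".csv"))
    cov <- list()
    pa_cov <- list()
    for (level in c("region", "subregion")) {
      ug <- bundle$unit_geoms[[nm]][[level]]
      for (tp in c("IBA", "AZE")) {
        sc <- site_coverage(bundle$sites, ug, tp)
        sc$level <- level
        cov[[length(cov) + 1]] <- sc[, c("unit", "level", "site_type",
                                         "n_sites", "mean_size_km2",
                                         "pct_cover")]
      }
      pc <- pa_coverage(bundle$pas, ug)
      pc$level <- level
      pa_cov[[length(pa_cov) + 1]] <- pc[, c("unit", "level", "pct_land",
                                             "pct_sea")]
    }
    emit(do.call(rbind, cov), paste0("IBAs_AZEs_", nm, ".csv"))
    emit(do.call(rbind, pa_cov), paste0("PAs_", nm, ".csv"))
    for (tp in c("IBA", "AZE")) {
      tr <- rbind(
        pa_trend_table(bundle$sites, bundle$pas,
                       bundle$unit_geoms[[nm]]$region, tp, "region",
                       years, n_reps, threshold, seed),
        pa_trend_table(bundle$sites, bundle$pas,
                       bundle$unit_geoms[[nm]]$subregion, tp, "subregion",
                       years, n_reps, threshold, seed))
      emit(tr, paste0("Protected_", tp, "s_", nm, ".csv"))
    }
  }
  invisible(written)
}
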