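# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain nested loops for tabulation, a raster
# grid for areas, direct formula evaluation for bounds.

# ---- brute-force species tabulation -------------------------------------

bf_excluded <- c("vagrant", "uncertain", "introduced")

# nested-loop tabulation over (unit, group, species); scheme_table is the
# raw data frame (iso3, region, subregion), special a character vector
bf_tabulate <- function(scheme_table, special, assessments, occurrences,
                        mode, level) {
  units <- unique(scheme_table[[level]])
  if (mode == "occurring") units <- c(units, special)
  groups <- c(unique(assessments$group), "All")
  cats <- c("EX", "EW", "CR", "EN", "VU", "NT", "LC", "DD", "NE")
  rows <- list()
  for (u in units) {
    members <- if (u %in% special) u else
      scheme_table$iso3[scheme_table[[level]] == u]
    for (g in groups) {
      sp_g <- if (g == "All") assessments$species_id else
        assessments$species_id[assessments$group == g]
      hits <- character()
      for (sp in sp_g) {
        recs <- occurrences[occurrences$species_id == sp, , drop = FALSE]
        recs <- recs[!tolower(recs$origin) %in% bf_excluded, , drop = FALSE]
        occurs <- any(recs$unit_code %in% members)
        if (!occurs) next
        if (mode == "endemic") {
          country_recs <- recs$unit_code[!recs$unit_code %in% special]
          if (!all(country_recs %in% members)) next
        }
        hits <- c(hits, sp)
      }
      cc <- sapply(cats, function(k) {
        sum(assessments$category[assessments$species_id %in% hits] == k)
      })
      total <- sum(cc) - cc[["NE"]]
      thr <- cc[["CR"]] + cc[["EN"]] + cc[["VU"]]
      pl <- if (total - cc[["EX"]] > 0) 100 * thr / (total - cc[["EX"]])
        else NA_real_
      pb <- if (total - cc[["EX"]] - cc[["DD"]] > 0) {
        100 * thr / (total - cc[["EX"]] - cc[["DD"]])
      } else NA_real_
      pu <- if (total - cc[["EX"]] > 0) {
        100 * (thr + cc[["DD"]]) / (total - cc[["EX"]])
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        unit = u, group = g, t(cc), total_assessed = total,
        pct_lower = pl, pct_best = pb, pct_upper = pu,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# random species tables over a synthetic scheme, for oracle comparisons
random_species_tables <- function(seed, n_countries = 30, n_species = 200,
                                  groups = c("g1", "g2")) {
  set.seed(seed)
  iso <- rlregions:::synthetic_iso3(n_countries)
  scheme_table <- data.frame(
    iso3 = iso,
    region = paste0("R", rep_len(1:3, n_countries)),
    subregion = paste0("S", rep_len(1:6, n_countries)),
    stringsAsFactors = FALSE)
  # keep subregions nested: recompute region from subregion index
  sub_idx <- as.integer(sub("S", "", scheme_table$subregion))
  scheme_table$region <- paste0("R", (sub_idx - 1) %/% 2 + 1)
  cats <- c("EX", "EW", "CR", "EN", "VU", "NT", "LC", "DD", "NE")
  assessments <- data.frame(
    species_id = sprintf("sp%03d", seq_len(n_species)),
    group = sample(groups, n_species, replace = TRUE),
    category = sample(cats, n_species, replace = TRUE,
                      prob = c(2, 1, 5, 8, 10, 12, 45, 12, 5)),
    stringsAsFactors = FALSE)
  occ <- list()
  for (i in seq_len(n_species)) {
    k <- sample(1:4, 1, prob = c(0.6, 0.2, 0.1, 0.1))
    u <- sample(iso, k)
    ori <- sample(c("native", "vagrant", "uncertain", "introduced",
                    "reintroduced"),
                  k, replace = TRUE, prob = c(0.7, 0.1, 0.07, 0.08, 0.05))
    rows <- data.frame(species_id = assessments$species_id[i],
                       unit_code = u, origin = ori,
                       stringsAsFactors = FALSE)
    if (runif(1) < 0.1) {
      rows <- rbind(rows, data.frame(species_id = assessments$species_id[i],
                                     unit_code = "ABNJ", origin = "native",
                                     stringsAsFactors = FALSE))
    }
    occ[[i]] <- rows
  }
  list(scheme_table = scheme_table,
       scheme = region_scheme(scheme_table, "oracle",
                              special_units = "ABNJ"),
       assessments = assessments,
       occurrences = do.call(rbind, occ))
}

# ---- rasterization oracle for areas -------------------------------------

# mark grid cells whose centre lies in any rectangle of rs
raster_mask <- function(rs, bbox, n = 1000) {
  cx <- bbox[1] + (seq_len(n) - 0.5) / n * (bbox[3] - bbox[1])
  cy <- bbox[2] + (seq_len(n) - 0.5) / n * (bbox[4] - bbox[2])
  m <- matrix(FALSE, n, n)
  df <- as.data.frame(rs)
  for (i in seq_len(nrow(df))) {
    xi <- which(cx >= df$xmin[i] & cx <= df$xmax[i])
    yi <- which(cy >= df$ymin[i] & cy <= df$ymax[i])
    if (length(xi) > 0 && length(yi) > 0) m[xi, yi] <- TRUE
  }
  m
}

raster_area <- function(rs, bbox, n = 1000) {
  cell <- (bbox[3] - bbox[1]) * (bbox[4] - bbox[2]) / n^2
  sum(raster_mask(rs, bbox, n)) * cell
}

# percentage of the unit mask covered by the layer mask
raster_pct <- function(layer_rs, unit_rs, bbox, n = 1000) {
  mu <- raster_mask(unit_rs, bbox, n)
  ml <- raster_mask(layer_rs, bbox, n)
  100 * sum(ml & mu) / sum(mu)
}

random_rectset <- function(k, xmax = 10, ymax = 10, min_side = 0.3,
                           max_side = 3) {
  x0 <- runif(k, 0, xmax - min_side)
  y0 <- runif(k, 0, ymax - min_side)
  w <- runif(k, min_side, max_side)
  h <- runif(k, min_side, max_side)
  rectset(x0, y0, pmin(x0 + w, xmax), pmin(y0 + h, ymax))
}
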