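demo_scheme <- function() {
  region_scheme(data.frame(
    iso3 = c("AFG", "IND", "FRA", "IDN"),
    region = c("Asia+Pacific", "Asia+Pacific", "Europe", "Asia+Pacific"),
    subregion = c("South Asia", "South Asia", "Western Europe",
                  "South East Asia")),
    scheme_name = "demo", special_units = "ABNJ")
}

test_that("occurrence respects the origin filter", {
  s <- demo_scheme()
  occ <- data.frame(
    species_id = c("a", "a", "b", "b", "c"),
    unit_code = c("AFG", "FRA", "AFG", "IND", "AFG"),
    origin = c("native", "introduced", "vagrant", "vagrant", "native"))
  expect_true("a" %in% species_occurring(occ, s, "Asia+Pacific", "region"))
  # vagrant-only everywhere: not occurring anywhere
  expect_false("b" %in% species_occurring(occ, s, "Asia+Pacific", "region"))
  expect_equal(species_occurring(occ[0, ], s, "Europe", "region"),
               character())
  expect_error(species_occurring(occ, s, "Nowhere", "region"), "Nowhere")
})

test_that("endemism excludes outside records but ignores excluded origins", {
  s <- demo_scheme()
  occ <- data.frame(
    species_id = c("a", "a", "b", "b", "c", "c"),
    unit_code = c("AFG", "IND", "AFG", "IDN", "AFG", "FRA"),
    origin = c("native", "native", "native", "native", "native",
               "introduced"))
  # a: AFG+IND, both in South Asia; c's only counting record is also AFG
  expect_equal(species_endemic(occ, s, "South Asia", "subregion"),
               c("a", "c"))
  expect_equal(species_endemic(occ, s, "South East Asia", "subregion"),
               character())
  # c: native AFG, introduced FRA -> introduced record excluded
  expect_true("c" %in% species_endemic(occ, s, "Asia+Pacific", "region"))
  # b spans two subregions of one region
  expect_true("b" %in% species_endemic(occ, s, "Asia+Pacific", "region"))
  expect_false("b" %in% species_endemic(occ, s, "South Asia", "subregion"))
  # endemism to ABNJ is rejected with a warning
  expect_warning(out <- species_endemic(occ, s, "ABNJ", "region"), "ABNJ")
  expect_equal(out, character())
})

test_that("an ABNJ record does not break endemism to a country region", {
  s <- demo_scheme()
  occ <- data.frame(
    species_id = c("a", "a"),
    unit_code = c("AFG", "ABNJ"),
    origin = c("native", "native"))
  expect_true("a" %in% species_endemic(occ, s, "Asia+Pacific", "region"))
  expect_true("a" %in% species_occurring(occ, s, "ABNJ", "region"))
})

test_that("category counts tally the set and flag missing assessments", {
  assess <- data.frame(species_id = c("a", "b", "c"),
                       group = "g",
                       category = c("CR", "LC", "DD"))
  cc <- category_counts(c("a", "b", "c"), assess)
  expect_equal(unname(cc[c("CR", "LC", "DD")]), c(1L, 1L, 1L))
  expect_equal(unname(cc["total_assessed"]), 3L)
  cc0 <- category_counts(character(), assess)
  expect_true(all(cc0 == 0))
  expect_error(category_counts(c("a", "zz"), assess), "zz")
  # NE stays outside total_assessed
  assess$category[2] <- "NE"
  expect_equal(unname(category_counts(c("a", "b"),
                                      assess)["total_assessed"]), 1L)
})

test_that("threat bounds follow the three printed formulas", {
  # CR=1, EN=1, VU=1, DD=1, LC=5, EX=1: total 10
  tb <- threat_bounds(c(CR = 1, EN = 1, VU = 1, DD = 1, LC = 5, EX = 1))
  expect_equal(unname(tb["pct_lower"]), 100 * 3 / 9)
  expect_equal(unname(tb["pct_best"]), 37.5)
  expect_equal(unname(tb["pct_upper"]), 100 * 4 / 9)
  # DD = 0 collapses the three onto one value
  tb0 <- threat_bounds(c(CR = 2, EN = 1, VU = 0, LC = 7))
  expect_equal(unname(tb0["pct_lower"]), unname(tb0["pct_best"]))
  expect_equal(unname(tb0["pct_best"]), unname(tb0["pct_upper"]))
  # all extinct: undefined, not an error
  expect_true(all(is.na(threat_bounds(c(EX = 4)))))
  # EW remains in the denominator
  tbw <- threat_bounds(c(CR = 1, EW = 1, LC = 2))
  expect_equal(unname(tbw["pct_best"]), 25)
})

test_that("unknown origin tokens default to native with a warning", {
  expect_warning(o <- normalize_origin(c("Native", "Origin Uncertain",
                                         "weird")), "weird")
  expect_equal(o, c("native", "uncertain", "native"))
  expect_equal(normalize_origin("Reintroduced"), "native")
})

test_that("tabulation equals the brute-force oracle and is order-invariant", {
  tabs <- random_species_tables(seed = 99, n_countries = 20,
                                n_species = 120)
  for (mode in c("occurring", "endemic")) {
    for (level in c("region", "subregion")) {
      got <- suppressWarnings(
        tabulate_units(tabs$scheme, tabs$assessments, tabs$occurrences,
                       mode = mode, level = level))
      want <- bf_tabulate(tabs$scheme_table, "ABNJ", tabs$assessments,
                          tabs$occurrences, mode, level)
      m <- merge(got, want, by = c("unit", "group"),
                 suffixes = c("", ".bf"))
      expect_equal(nrow(m), nrow(got))
      for (col in c("CR", "DD", "LC", "total_assessed")) {
        expect_equal(m[[col]], m[[paste0(col, ".bf")]],
                     info = paste(mode, level, col))
      }
      expect_equal(m$pct_best, m$pct_best.bf, tolerance = 1e-12)
    }
  }
  # permutation invariance over record order
  perm <- tabs$occurrences[sample(nrow(tabs$occurrences)), ]
  t1 <- suppressWarnings(tabulate_units(tabs$scheme, tabs$assessments,
                                        tabs$occurrences, "occurring"))
  t2 <- suppressWarnings(tabulate_units(tabs$scheme, tabs$assessments,
                                        perm, "occurring"))
  expect_equal(t1, t2)
})

test_that("endemic counts never exceed occurring counts", {
  tabs <- random_species_tables(seed = 7, n_countries = 15, n_species = 80)
  occ <- suppressWarnings(tabulate_units(tabs$scheme, tabs$assessments,
                                         tabs$occurrences, "occurring"))
  end <- suppressWarnings(tabulate_units(tabs$scheme, tabs$assessments,
                                         tabs$occurrences, "endemic"))
  m <- merge(end, occ, by = c("unit", "level", "group"),
             suffixes = c(".end", ".occ"))
  expect_true(all(m$total_assessed.end <= m$total_assessed.occ))
  # each species is endemic to at most one unit per level: totals bounded
  n_all <- nrow(tabs$assessments)
  for (lv in c("region", "subregion")) {
    tot <- sum(end$total_assessed[end$level == lv & end$group == "All"])
    expect_lte(tot, n_all)
  }
})
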