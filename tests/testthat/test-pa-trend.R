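trend_world <- function(seed) {
  world_spec(n_countries = 12,
             schemes = list(SYNA = c(n_regions = 3,
                                     n_subregions_per_region = 2)),
             n_species_per_group = 2, groups = "birds",
             n_iba = 20, n_aze = 8, n_pas = 60,
             undated_pa_fraction = c(terrestrial = 0.15, marine = 0.15),
             seed = seed)
}

simple_sites <- function() {
  sites <- data.frame(site_id = "s1", site_type = "IBA",
                      stringsAsFactors = FALSE)
  sites$geometry <- I(list(rectset(0, 0, 1, 1)))
  sites
}

pa_table <- function(ids, years, rects, realm = "terrestrial",
                     country = "AAA") {
  pas <- data.frame(pa_id = ids, country_code = country, realm = realm,
                    year_established = years, stringsAsFactors = FALSE)
  pas$geometry <- I(rects)
  pas
}

test_that("whole-coverage detection handles unions and thresholds", {
  sites <- simple_sites()
  pas <- pa_table(c("p1", "p2", "p3"), c(1990, 1995, 2000),
                  list(rectset(0, 0, 1, 1),        # full cover
                       rectset(0, 0, 0.5, 1),      # left half
                       rectset(0.5, 0, 1, 1)))     # right half
  prof <- site_protection_profiles(sites, pas)[[1]]
  expect_true(site_wholly_covered(prof, "p1", 0.98))
  expect_false(site_wholly_covered(prof, "p2", 0.98))
  # two halves together complete the cover
  expect_true(site_wholly_covered(prof, c("p2", "p3"), 0.98))
  expect_true(site_wholly_covered(prof, c("p2", "p3"), 1))
  # 50% cover fails at 0.98 but passes at 0.5
  expect_true(site_wholly_covered(prof, "p2", 0.5))
})

test_that("coverage series is a step function of establishment years", {
  sites <- simple_sites()
  pas <- pa_table("p1", 1995, list(rectset(0, 0, 1, 1)))
  s <- coverage_series(sites, pas, 1990:2000)
  expect_equal(s, c(rep(0, 5), rep(100, 6)))
  # union completes cover only when the later half arrives
  pas2 <- pa_table(c("p1", "p2"), c(1990, 1998),
                   list(rectset(0, 0, 0.5, 1), rectset(0.5, 0, 1, 1)))
  s2 <- coverage_series(sites, pas2, 1990:2000)
  expect_equal(s2, ifelse(1990:2000 >= 1998, 100, 0))
  # no protected areas at all: flat zero
  s3 <- coverage_series(sites, pas2[0, ], 1990:2000)
  expect_equal(s3, rep(0, 11))
  # series are non-decreasing by construction
  expect_true(all(diff(s2) >= 0))
})

test_that("brute-force per-year recomputation agrees with the series", {
  set.seed(17)
  w <- generate_world(trend_world(4))
  pas <- w$pas
  pas$year_established <- as.numeric(w$truth$true_years[pas$pa_id])
  st <- w$sites[w$sites$site_type == "IBA", , drop = FALSE]
  years <- seq(1980, 2010, by = 5)
  got <- coverage_series(st, pas, years)
  profs <- site_protection_profiles(st, pas)
  for (k in seq_along(years)) {
    active <- pas$pa_id[pas$year_established <= years[k]]
    covered <- vapply(profs, site_wholly_covered, logical(1),
                      active_pa_ids = active, threshold = 0.98)
    expect_equal(got[k], 100 * mean(covered))
  }
})

test_that("imputation pools follow the five-dated-records rule", {
  pas <- pa_table(sprintf("p%d", 1:8),
                  c(1990, 1991, 1992, 1993, 1994, 2000, 2001, NA),
                  rep(list(rectset(0, 0, 1, 1)), 8),
                  country = c(rep("AAA", 5), rep("BBB", 3)))
  pools <- imputation_pools(pas)
  # AAA has 5 dated: country pool
  expect_equal(sort(rlregions:::pool_for(pools, "AAA", "terrestrial")),
               1990:1994)
  # BBB has only 2 dated: falls back to the realm-wide pool (7 years)
  expect_length(rlregions:::pool_for(pools, "BBB", "terrestrial"), 7)
  # imputation fills only the undated row
  set.seed(1)
  done <- impute_years(pas, pools)
  expect_false(anyNA(done$year_established))
  expect_equal(done$year_established[1:7], pas$year_established[1:7])
  expect_true(done$year_established[8] %in%
                pas$year_established[1:7])
  # no undated records: no-op for any seed
  expect_identical(impute_years(pas[1:7, ], pools), pas[1:7, ])
  # empty realm pool is an error
  pm <- pa_table("m1", NA, list(rectset(0, 0, 1, 1)), realm = "marine")
  expect_error(impute_years(pm, imputation_pools(pm)), "marine")
})

test_that("imputation draws are uniform over the pool", {
  pas <- pa_table(sprintf("p%d", 1:3), c(1990, 2000, NA),
                  rep(list(rectset(0, 0, 1, 1)), 3))
  pools <- imputation_pools(pas, min_dated = 2)
  set.seed(8)
  draws <- replicate(10000, impute_years(pas, pools)$year_established[3])
  p_hat <- mean(draws == 1990)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("a fully dated estate gives a degenerate envelope", {
  set.seed(2)
  w <- generate_world(trend_world(11))
  pas <- w$pas
  pas$year_established <- as.numeric(w$truth$true_years[pas$pa_id])
  st <- w$sites[w$sites$site_type == "IBA", , drop = FALSE]
  tr <- trend_with_ci(st, pas, seq(1960, 2015, 5), n_reps = 7, seed = 99)
  expect_equal(tr$ci_low, tr$median_pct)
  expect_equal(tr$ci_high, tr$median_pct)
  expect_true(all(diff(tr$median_pct) >= 0))
})

test_that("trend is reproducible and respects ordering invariants", {
  w <- generate_world(trend_world(5))
  st <- w$sites[w$sites$site_type == "IBA", , drop = FALSE]
  years <- seq(1960, 2015, 5)
  t1 <- trend_with_ci(st, w$pas, years, n_reps = 30, seed = 123,
                      keep_replicates = TRUE)
  t2 <- trend_with_ci(st, w$pas, years, n_reps = 30, seed = 123)
  expect_equal(t1$median_pct, t2$median_pct)
  expect_equal(t1$ci_low, t2$ci_low)
  expect_equal(t1$ci_high, t2$ci_high)
  # envelope ordering and monotonicity of every summary series
  expect_true(all(t1$ci_low <= t1$median_pct + 1e-12))
  expect_true(all(t1$median_pct <= t1$ci_high + 1e-12))
  for (s in list(t1$median_pct, t1$ci_low, t1$ci_high)) {
    expect_true(all(diff(s) >= 0))
  }
  # every replicate is monotone too
  expect_true(all(apply(t1$replicates, 1, function(r) all(diff(r) >= 0))))
})

test_that("raising the threshold never increases coverage", {
  w <- generate_world(trend_world(6))
  pas <- w$pas
  pas$year_established <- as.numeric(w$truth$true_years[pas$pa_id])
  st <- w$sites[w$sites$site_type == "IBA", , drop = FALSE]
  years <- seq(1960, 2015, 5)
  lo <- coverage_series(st, pas, years, threshold = 0.5)
  hi <- coverage_series(st, pas, years, threshold = 0.98)
  strict <- coverage_series(st, pas, years, threshold = 1)
  expect_true(all(hi <= lo))
  expect_true(all(strict <= hi))
})

test_that("narrowing the undated fraction shrinks the envelope to zero", {
  widths <- vapply(c(0, 0.05, 0.15), function(f) {
    spec <- trend_world(21)
    spec$undated_pa_fraction <- c(terrestrial = f, marine = f)
    w <- generate_world(spec)
    st <- w$sites[w$sites$site_type == "IBA", , drop = FALSE]
    tr <- trend_with_ci(st, w$pas, seq(1960, 2015, 5), n_reps = 40,
                        seed = 1)
    mean(tr$ci_high - tr$ci_low)
  }, numeric(1))
  expect_equal(widths[1], 0)
  expect_true(widths[1] <= widths[2] + 1e-9)
  expect_true(widths[2] <= widths[3] + 1e-9)
})
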