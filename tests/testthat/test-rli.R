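test_that("category ranks follow the index ordering", {
  expect_equal(category_rank("LC"), 0L)
  expect_equal(category_rank("NT"), 1L)
  expect_equal(category_rank("VU"), 2L)
  expect_equal(category_rank("EN"), 3L)
  expect_equal(category_rank("CR"), 4L)
  expect_equal(category_rank("EW"), 5L)
  expect_equal(category_rank("EX"), 5L)
  # Possibly Extinct CR ranks with EW/EX
  expect_equal(category_rank("CR", "PE"), 5L)
  expect_equal(category_rank("CR", "PEW"), 5L)
  expect_lt(category_rank("EN"), category_rank("CR"))
  expect_error(category_rank("DD"), "not rankable")
  expect_error(category_rank("NE"), "not rankable")
  expect_error(category_rank("EN", "PE"), "CR")
})

test_that("category pairs decompose into unit steps with the right sign", {
  # deterioration by two categories: two -1 events
  ev <- events_from_category_pair("VU", "CR", genuine = TRUE)
  expect_equal(ev$step, c(-1L, -1L))
  # improvement: +1
  ev <- events_from_category_pair("CR", "EN", genuine = TRUE)
  expect_equal(ev$step, 1L)
  expect_equal(nrow(events_from_category_pair("EN", "EN", TRUE)), 0)
  expect_equal(nrow(events_from_category_pair("VU", "CR", FALSE)), 0)
  # CR -> CR(PE) is one step up the ladder
  ev <- events_from_category_pair("CR", "CR", TRUE, "none", "PE")
  expect_equal(ev$step, -1L)
})

test_that("decomposition drops unrankable endpoints with a warning", {
  changes <- data.frame(
    species_id = c("a", "b", "c"), group = "g",
    cat_start = c("LC", "DD", "VU"), cat_end = c("VU", "VU", "LC"),
    genuine = TRUE)
  expect_warning(ev <- decompose_changes(changes), "b")
  expect_equal(sum(ev$species_id == "a"), 2)
  expect_equal(sum(ev$species_id == "b"), 0)
  expect_equal(sum(ev$step[ev$species_id == "c"]), 2)
})

test_that("weighted annual change evaluates the downscaling formula", {
  scheme <- region_scheme(data.frame(
    iso3 = c("AAA", "BBB"), region = c("A", "B"),
    subregion = c("A1", "B1")), "t", special_units = "ABNJ")
  per <- assessment_period(2000, 2010)
  # one species, one deterioration, whole range in A: -1/10 in A only
  ev <- data.frame(species_id = "s1", step = -1L)
  fr <- data.frame(species_id = "s1", unit = "A", fraction = 1)
  w <- weighted_annual_change(ev, fr, per, scheme, "region")
  expect_equal(w$value[w$unit == "A"], -0.1)
  expect_equal(w$value[w$unit == "B"], 0)
  # split range weights the contribution
  fr2 <- data.frame(species_id = "s1", unit = c("A", "B"),
                    fraction = c(0.25, 0.75))
  w2 <- weighted_annual_change(ev, fr2, per, scheme, "region")
  expect_equal(w2$value[w2$unit == "A"], -0.025)
  expect_equal(w2$value[w2$unit == "B"], -0.075)
  # +1 and -1 cancel
  ev3 <- data.frame(species_id = c("s1", "s1"), step = c(1L, -1L))
  w3 <- weighted_annual_change(ev3, fr2, per, scheme, "region")
  expect_true(all(w3$value == 0))
  # no events: all zero
  w0 <- weighted_annual_change(ev[0, ], fr, per, scheme, "region")
  expect_true(all(w0$value == 0))
  # missing fractions are an error naming the species
  expect_error(
    weighted_annual_change(data.frame(species_id = "nope", step = -1L),
                           fr, per, scheme, "region"),
    "nope")
  # unnormalized fractions are an error, not silently rescaled
  frbad <- data.frame(species_id = "s1", unit = "A", fraction = 0.5)
  expect_error(weighted_annual_change(ev, frbad, per, scheme, "region"),
               "sum to 1")
})

test_that("unit contributions add up to the global annual change", {
  set.seed(31)
  scheme <- region_scheme(data.frame(
    iso3 = c("AAA", "BBB", "CCC"),
    region = c("A", "B", "C"), subregion = c("A1", "B1", "C1")), "t")
  per <- assessment_period(1993, 2013)
  for (rep in 1:20) {
    n_sp <- 15
    ids <- sprintf("s%02d", 1:n_sp)
    ev <- do.call(rbind, lapply(ids, function(s) {
      m <- rpois(1, 1.2)
      if (m == 0) return(NULL)
      data.frame(species_id = s,
                 step = sample(c(-1L, 1L), m, replace = TRUE))
    }))
    fr <- do.call(rbind, lapply(ids, function(s) {
      w <- rexp(3); w <- w / sum(w)
      data.frame(species_id = s, unit = c("A", "B", "C"), fraction = w)
    }))
    if (is.null(ev)) next
    w <- weighted_annual_change(ev, fr, per, scheme, "region")
    expect_lt(abs(additivity_check(w, ev, per)), 1e-9)
  }
  # negative control: fractions summing to 0.5 leave half the change
  ev <- data.frame(species_id = "s1", step = -1L)
  fr <- data.frame(species_id = "s1", unit = "A", fraction = 0.5)
  contrib <- sum(fr$fraction * -1) / per$years
  expect_equal(contrib, -1 / per$years / 2)
})

test_that("doubling the period halves every contribution", {
  scheme <- region_scheme(data.frame(
    iso3 = c("AAA", "BBB"), region = c("A", "B"),
    subregion = c("A1", "B1")), "t")
  ev <- data.frame(species_id = c("s1", "s2", "s2"),
                   step = c(-1L, -1L, 1L))
  fr <- data.frame(species_id = c("s1", "s1", "s2", "s2"),
                   unit = c("A", "B", "A", "B"),
                   fraction = c(0.3, 0.7, 1, 0))
  w1 <- weighted_annual_change(ev, fr, 10, scheme, "region")
  w2 <- weighted_annual_change(ev, fr, 20, scheme, "region")
  expect_equal(w2$value, w1$value / 2)
})

test_that("an endemic species contributes only to its own unit", {
  scheme <- region_scheme(data.frame(
    iso3 = c("AAA", "BBB"), region = c("A", "B"),
    subregion = c("A1", "B1")), "t")
  ev <- data.frame(species_id = "s1", step = c(-1L, -1L))
  fr <- data.frame(species_id = "s1", unit = "A", fraction = 1)
  w <- weighted_annual_change(ev, fr, 10, scheme, "region")
  expect_equal(w$value[w$unit == "A"], -0.2)
  expect_true(all(w$value[w$unit != "A"] == 0))
})
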