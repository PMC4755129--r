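unit_square_world <- function() {
  # one unit: land [0,1]x[0,0.5], sea [0,1]x[0.5,1]
  unit_geometry("U1",
                list(rectset(0, 0, 1, 0.5)),
                list(rectset(0, 0.5, 1, 1)))
}

test_that("site coverage on constructed half-cover cases", {
  ug <- unit_square_world()
  sites <- data.frame(site_id = "s1", site_type = "IBA",
                      stringsAsFactors = FALSE)
  sites$geometry <- I(list(rectset(0, 0, 1, 0.5)))  # exactly the land half
  cs <- site_coverage(sites, ug, "IBA")
  expect_equal(cs$n_sites, 1L)
  expect_equal(cs$pct_cover, 50)
  expect_equal(cs$mean_size_km2, 0.5)
  # no sites of the other type
  cs0 <- site_coverage(sites, ug, "AZE")
  expect_equal(cs0$n_sites, 0L)
  expect_true(is.na(cs0$mean_size_km2))
  expect_equal(cs0$pct_cover, 0)
  # unit with no surface: percentage undefined
  ug2 <- unit_geometry(c("U1", "EMPTY"),
                       list(rectset(0, 0, 1, 0.5), rectset()),
                       list(rectset(0, 0.5, 1, 1), rectset()))
  cs2 <- site_coverage(sites, ug2, "IBA")
  expect_true(is.na(cs2$pct_cover[cs2$unit == "EMPTY"]))
})

test_that("overlapping sites are dissolved before measuring coverage", {
  ug <- unit_square_world()
  sites <- data.frame(site_id = c("s1", "s2"),
                      site_type = "IBA", stringsAsFactors = FALSE)
  # two sites covering the same quarter: coverage counts it once
  sites$geometry <- I(list(rectset(0, 0, 0.5, 0.5),
                           rectset(0, 0, 0.5, 0.5)))
  cs <- site_coverage(sites, ug, "IBA")
  expect_equal(cs$n_sites, 2L)
  expect_equal(cs$pct_cover, 25)
})

test_that("protected-area coverage splits by realm and handles nesting", {
  ug <- unit_square_world()
  pas <- data.frame(pa_id = c("p1", "p2", "p3"),
                    realm = c("terrestrial", "terrestrial", "marine"),
                    stringsAsFactors = FALSE)
  # p2 nested inside p1; p3 covers all sea
  pas$geometry <- I(list(rectset(0, 0, 1, 0.5),
                         rectset(0.2, 0.1, 0.4, 0.3),
                         rectset(0, 0.5, 1, 1)))
  pc <- pa_coverage(pas, ug)
  expect_equal(pc$pct_land, 100)
  expect_equal(pc$pct_sea, 100)
  # landlocked unit: sea percentage undefined
  ug2 <- unit_geometry("L", list(rectset(0, 0, 1, 0.5)), list(rectset()))
  pc2 <- pa_coverage(pas, ug2)
  expect_true(is.na(pc2$pct_sea))
  # adding a protected area never decreases coverage
  pas3 <- pas[1:2, ]
  pas3$geometry <- I(list(rectset(0, 0, 0.3, 0.5),
                          rectset(0.6, 0, 0.9, 0.2)))
  one <- pa_coverage(pas3[1, ], ug)
  both <- pa_coverage(pas3, ug)
  expect_gte(both$pct_land, one$pct_land)
})

test_that("point-only protected areas are excluded from coverage", {
  ug <- unit_square_world()
  pas <- data.frame(pa_id = c("p1", "p2"),
                    realm = c("terrestrial", "terrestrial"),
                    stringsAsFactors = FALSE)
  pas$geometry <- I(list(rectset(0, 0, 0.5, 0.5), rectset()))
  expect_message(pc <- pa_coverage(pas, ug), "without polygon")
  expect_equal(pc$pct_land, 50)
})

test_that("coverage percentages match the rasterization oracle", {
  set.seed(23)
  for (rep in 1:6) {
    bbox <- c(0, 0, 10, 10)
    ug <- unit_geometry(c("A", "B"),
                        list(rectset(0, 0, 5, 5), rectset(5, 0, 10, 5)),
                        list(rectset(0, 5, 5, 10), rectset(5, 5, 10, 10)))
    n_sites <- 12
    sites <- data.frame(site_id = sprintf("s%02d", 1:n_sites),
                        site_type = "IBA", stringsAsFactors = FALSE)
    sites$geometry <- I(lapply(1:n_sites, function(i) random_rectset(1)))
    cs <- site_coverage(sites, ug, "IBA")
    merged <- dissolve(sites$geometry)
    for (i in 1:2) {
      unit_total <- dissolve(ug$land[[i]], ug$sea[[i]])
      want <- raster_pct(merged, unit_total, bbox, n = 1000)
      expect_lt(abs(cs$pct_cover[i] - want), 1)
    }
    pas <- data.frame(pa_id = sprintf("p%02d", 1:15),
                      realm = sample(c("terrestrial", "marine"), 15,
                                     replace = TRUE),
                      stringsAsFactors = FALSE)
    pas$geometry <- I(lapply(1:15, function(i) random_rectset(1)))
    pc <- pa_coverage(pas, ug)
    land_layer <- dissolve(pas$geometry[pas$realm == "terrestrial"])
    for (i in 1:2) {
      want <- raster_pct(land_layer, ug$land[[i]], bbox, n = 1000)
      expect_lt(abs(pc$pct_land[i] - want), 1)
    }
  }
})

test_that("subregion dissolved areas partition the region's", {
  # region = two subregion halves; sites straddling the boundary
  set.seed(9)
  region <- unit_geometry("R", list(rectset(0, 0, 10, 5)),
                          list(rectset(0, 5, 10, 10)))
  subs <- unit_geometry(c("S1", "S2"),
                        list(rectset(0, 0, 5, 5), rectset(5, 0, 10, 5)),
                        list(rectset(0, 5, 5, 10), rectset(5, 5, 10, 10)))
  layer <- random_rectset(10)
  region_total <- dissolve(region$land[[1]], region$sea[[1]])
  a_region <- rs_area(rs_intersect(layer, region_total))
  a_subs <- sum(vapply(1:2, function(i) {
    rs_area(rs_intersect(layer, dissolve(subs$land[[i]], subs$sea[[i]])))
  }, numeric(1)))
  expect_equal(a_subs, a_region, tolerance = 1e-12)
})

test_that("statistics are translation invariant", {
  set.seed(41)
  ug <- unit_square_world()
  sites <- data.frame(site_id = "s", site_type = "IBA",
                      stringsAsFactors = FALSE)
  sites$geometry <- I(list(rectset(0.1, 0.1, 0.6, 0.4)))
  base <- site_coverage(sites, ug, "IBA")
  dx <- 7.5; dy <- -2.25
  ug2 <- unit_geometry("U1", list(rs_translate(ug$land[[1]], dx, dy)),
                       list(rs_translate(ug$sea[[1]], dx, dy)))
  sites2 <- sites
  sites2$geometry <- I(list(rs_translate(sites$geometry[[1]], dx, dy)))
  moved <- site_coverage(sites2, ug2, "IBA")
  expect_equal(moved$pct_cover, base$pct_cover)
  expect_equal(moved$mean_size_km2, base$mean_size_km2)
})
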