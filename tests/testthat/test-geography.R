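test_that("haversine distance matches closed-form arcs and is symmetric", {
  expect_equal(haversine_distance(10, 20, 10, 20), 0)
  # antipodal points: half the circumference of the 6371 km sphere
  expect_equal(haversine_distance(0, 0, 0, 180), 6371 * pi, tolerance = 1e-12)
  # one degree of arc along the equator
  expect_equal(haversine_distance(0, 0, 0, 1), 6371 * pi / 180, tolerance = 1e-12)
  set.seed(7)
  la1 <- runif(20, -90, 90); lo1 <- runif(20, -180, 180)
  la2 <- runif(20, -90, 90); lo2 <- runif(20, -180, 180)
  expect_equal(haversine_distance(la1, lo1, la2, lo2),
               haversine_distance(la2, lo2, la1, lo1))
  expect_true(all(haversine_distance(la1, lo1, la2, lo2) >= 0))
})

test_that("haversine agrees with an independent geodesic implementation", {
  set.seed(11)
  la1 <- runif(25, -80, 80); lo1 <- runif(25, -180, 180)
  la2 <- runif(25, -80, 80); lo2 <- runif(25, -180, 180)
  ref <- geosphere::distHaversine(cbind(lo1, la1), cbind(lo2, la2),
                                  r = 6371000) / 1000
  expect_equal(haversine_distance(la1, lo1, la2, lo2), ref, tolerance = 1e-10)
})

test_that("coordinate validation names the offending field", {
  expect_error(haversine_distance(91, 0, 0, 0), "latitude")
  expect_error(haversine_distance(0, -200, 0, 0), "longitude")
})

test_that("urbanicity classification is strict at the threshold and monotone", {
  expect_equal(classify_urbanicity(0.60, 0.5), "urban")
  expect_equal(classify_urbanicity(0.05, 0.1), "rural")
  expect_equal(classify_urbanicity(0.5, 0.5), "rural")   # tie goes to rural
  expect_equal(classify_urbanicity(0.11, 0.1), "urban")
  fr <- seq(0, 1, by = 0.05)
  lab <- classify_urbanicity(fr, 0.4)
  expect_true(all(diff(lab == "urban") >= 0))  # monotone in the fraction
  expect_error(classify_urbanicity(1.2), "\\[0, 1\\]")
  expect_error(classify_urbanicity(0.5, -0.1), "\\[0, 1\\]")
})

test_that("geography builds a symmetric zero-diagonal distance matrix", {
  geo <- test_geography()
  d <- geo$distance
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(all(d[upper.tri(d)] > 0))
  expect_equal(geo$total_population, sum(test_districts()$population))
  # element-wise brute-force recomputation
  dd <- test_districts()
  for (i in 1:5) for (j in 1:5)
    expect_equal(d[i, j],
                 haversine_distance(dd$lat[i], dd$lon[i], dd$lat[j], dd$lon[j]),
                 tolerance = 1e-12)
})

test_that("distance matrix satisfies the triangle inequality", {
  geo <- random_geography(3, n = 8)
  d <- geo$distance
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
})

test_that("coincident centroids give zero distance", {
  dd <- test_districts()[1:2, ]
  dd$lat <- c(10, 10); dd$lon <- c(1, 1)
  geo <- geography(dd)
  expect_equal(unname(geo$distance), matrix(0, 2, 2))
})

test_that("district table validation lists offenders", {
  dd <- test_districts()
  d2 <- dd; d2$id[2] <- "a"
  expect_error(geography(d2), "duplicate district ids: a")
  expect_error(geography(dd[, -4]), "missing columns: population")
  expect_error(geography(dd[1, , drop = FALSE]), "at least 2")
  d3 <- dd; d3$population[1] <- 0
  expect_error(geography(d3), "population")
})

test_that("district CSV round-trips", {
  dd <- test_districts()
  path <- withr::local_tempfile(fileext = ".csv")
  write_districts(dd, path)
  back <- read_districts(path)
  expect_equal(back$id, dd$id)
  expect_equal(back$population, dd$population)
  expect_equal(back$urban_fraction, dd$urban_fraction)
})

test_that("GeoJSON polygons reduce to the standard area centroid", {
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = list(id = "p1", name = "Poly 1", region_id = "r1",
                      population = 1000, urban_fraction = 0.2),
    geometry = list(type = "Polygon", coordinates = list(list(
      list(0, 0), list(2, 0), list(2, 2), list(0, 2), list(0, 0)
    )))
  ), list(
    type = "Feature",
    properties = list(id = "p2", name = "Poly 2", region_id = "r1",
                      population = 2000, urban_fraction = 0.6),
    # L-shaped polygon: area centroid differs from the vertex mean
    geometry = list(type = "Polygon", coordinates = list(list(
      list(4, 0), list(8, 0), list(8, 1), list(5, 1), list(5, 4),
      list(4, 4), list(4, 0)
    )))
  )))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  dd <- read_districts_geojson(path)
  expect_equal(dd$lon[1], 1); expect_equal(dd$lat[1], 1)
  # shoelace centroid of the L: area 7, moments by decomposition
  # rectangle 4x1 (centroid 6, 0.5) + rectangle 1x3 (centroid 4.5, 2.5)
  expect_equal(dd$lon[2], (4 * 6 + 3 * 4.5) / 7, tolerance = 1e-12)
  expect_equal(dd$lat[2], (4 * 0.5 + 3 * 2.5) / 7, tolerance = 1e-12)
})

test_that("aggregation conserves population and between-unit trips", {
  geo <- test_geography()
  set.seed(5)
  trips <- matrix(rpois(25, 40), 5, 5, dimnames = list(geo$districts$id,
                                                       geo$districts$id))
  diag(trips) <- NA
  # identity mapping: unchanged up to diagonal removal
  idmap <- setNames(geo$districts$id, geo$districts$id)
  same <- aggregate_geography(geo, idmap, trips)
  expect_equal(same$geography$distance, geo$distance)
  expect_equal(same$geography$districts$population, geo$districts$population)
  expect_equal(same$trips[!is.na(same$trips)], trips[!is.na(trips)])

  # everything into one unit: no between-unit trips remain
  onemap <- setNames(rep("u1", 5), geo$districts$id)
  one <- aggregate_geography(geo, onemap, trips)
  expect_equal(nrow(one$geography$districts), 1L)
  expect_true(all(is.na(one$trips)))
  expect_equal(one$geography$total_population, geo$total_population)

  # 4 -> 2 toy against hand enumeration of member pairs
  g4 <- geography(test_districts()[1:4, ])
  t4 <- trips[1:4, 1:4]
  map <- setNames(c("u1", "u1", "u2", "u2"), g4$districts$id)
  agg <- aggregate_geography(g4, map, t4)
  expect_equal(agg$trips["u1", "u2"], t4[1, 3] + t4[1, 4] + t4[2, 3] + t4[2, 4])
  expect_equal(agg$trips["u2", "u1"], t4[3, 1] + t4[3, 2] + t4[4, 1] + t4[4, 2])
  expect_equal(agg$geography$districts$population,
               c(sum(g4$districts$population[1:2]), sum(g4$districts$population[3:4])))
  # population-weighted centroid and urban fraction
  w <- g4$districts$population[1:2] / sum(g4$districts$population[1:2])
  expect_equal(agg$geography$districts$lat[1], sum(w * g4$districts$lat[1:2]))
  expect_equal(agg$geography$districts$urban_fraction[1],
               sum(w * g4$districts$urban_fraction[1:2]))
  # conservation: total trips minus within-unit trips, exactly
  within <- t4[1, 2] + t4[2, 1] + t4[3, 4] + t4[4, 3]
  expect_equal(sum(agg$trips, na.rm = TRUE), sum(t4, na.rm = TRUE) - within)
  expect_error(aggregate_geography(g4, map[1:3], t4), "missing districts")
})

test_that("districts with no trip data are dropped before fitting", {
  geo <- test_geography()
  trips <- matrix(20, 5, 5, dimnames = list(geo$districts$id, geo$districts$id))
  diag(trips) <- NA
  trips["c", ] <- NA; trips[, "c"] <- NA
  expect_message(out <- drop_missing_districts(trips, geo), "c")
  expect_equal(out$dropped, "c")
  expect_equal(nrow(out$geography$districts), 4L)
  expect_false("c" %in% rownames(out$trips))
})
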