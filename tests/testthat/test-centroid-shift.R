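test_that("period assignment splits the season at February 6/7", {
  expect_equal(as.character(assign_period(as.Date("2021-02-06"))), "early")
  expect_equal(as.character(assign_period(as.Date("2021-02-07"))), "late")
  expect_equal(as.character(assign_period(as.Date("2021-01-01"))), "early")
  expect_error(assign_period(as.Date("2021-03-03")), "season window")
  expect_error(assign_period(as.Date("2020-02-29")), "season window")

  days <- seq(as.Date("2021-01-01"), as.Date("2021-02-28"), by = 1)
  p <- assign_period(days)
  expect_equal(sum(p == "early"), 37)
  expect_equal(sum(p == "late"), 22)
})

test_that("weighted centroid is the closed-form weighted mean", {
  one <- weighted_centroid(tibble::tibble(lat = 35, lon = -89, count = 4))
  expect_equal(c(one$lat, one$lon), c(35, -89))

  two <- weighted_centroid(
    tibble::tibble(lat = c(34, 36), lon = -90, count = c(1, 3))
  )
  expect_equal(two$lat, 35.5)
  expect_equal(two$lon, -90)

  set.seed(9)
  rows <- tibble::tibble(
    lat = runif(50, 30, 40), lon = runif(50, -95, -85),
    count = rpois(50, 6) + 1
  )
  got <- weighted_centroid(rows)
  # independent element-by-element summation oracle
  sl <- 0; sn <- 0; sw <- 0
  for (i in 1:50) {
    sl <- sl + rows$count[i] * rows$lat[i]
    sn <- sn + rows$count[i] * rows$lon[i]
    sw <- sw + rows$count[i]
  }
  expect_equal(got$lat, sl / sw, tolerance = 1e-12)
  expect_equal(got$lon, sn / sw, tolerance = 1e-12)
  expect_equal(got$total_weight, sw)

  scaled <- rows; scaled$count <- scaled$count * 7.5
  expect_equal(weighted_centroid(scaled)$lat, got$lat, tolerance = 1e-12)
  shuffled <- rows[sample(50), ]
  expect_equal(weighted_centroid(shuffled)$lat, got$lat, tolerance = 1e-12)
  expect_gte(got$lat, min(rows$lat)); expect_lte(got$lat, max(rows$lat))
  expect_gte(got$lon, min(rows$lon)); expect_lte(got$lon, max(rows$lon))

  expect_error(weighted_centroid(rows[0, ]), "positive")
  zero <- rows; zero$count <- 0
  expect_error(weighted_centroid(zero), "positive")
})

test_that("GPS centroid weightings agree when weights are fix counts", {
  same <- tibble::tibble(lat = 35.2, lon = -88.1, region = "TN")[rep(1, 5), ]
  expect_equal(gps_centroid(same, "plain")$lat, 35.2)
  expect_equal(gps_centroid(same, "by_region")$lat, 35.2)

  two <- tibble::tibble(
    lat = c(rep(34, 9), rep(36, 1)), lon = -90,
    region = c(rep("AR", 9), rep("TN", 1))
  )
  expect_equal(gps_centroid(two, "by_region")$lat, 34.2)

  set.seed(4)
  fixes <- tibble::tibble(
    lat = runif(200, 33, 37), lon = runif(200, -92, -87),
    region = sample(c("AR", "TN"), 200, replace = TRUE, prob = c(0.3, 0.7))
  )
  expect_equal(
    gps_centroid(fixes, "plain")$lat,
    gps_centroid(fixes, "by_region")$lat,
    tolerance = 1e-12
  )
  expect_error(gps_centroid(fixes[0, ]), "at least one fix")
})

test_that("shift distance has haversine magnitude and latitudinal sign", {
  a <- tibble::tibble(lat = 34, lon = -90)
  b <- tibble::tibble(lat = 35, lon = -90)
  expect_equal(shift_distance(a, a), 0)
  expect_lt(abs(shift_distance(a, b) - 111.19), 0.01)
  expect_equal(shift_distance(b, a), -shift_distance(a, b))

  set.seed(12)
  n <- 1000
  p <- tibble::tibble(lat = runif(n, -60, 60), lon = runif(n, -170, 170))
  q <- tibble::tibble(lat = runif(n, -60, 60), lon = runif(n, -170, 170))
  got <- abs(shift_distance(p, q))
  want <- oracle_sloc_km(p$lat, p$lon, q$lat, q$lon)
  expect_lt(max(abs(got - want) / pmax(want, 1)), 1e-6)
  expect_equal(shift_distance(q, p), -shift_distance(p, q))
})

test_that("haversine agrees with an established geodesy backend", {
  skip_if_not_installed("geosphere")
  set.seed(2)
  p <- cbind(runif(100, -170, 170), runif(100, -60, 60))
  q <- cbind(runif(100, -170, 170), runif(100, -60, 60))
  want <- geosphere::distHaversine(p, q, r = 6371008.8) / 1000
  got <- haversine_km(p[, 2], p[, 1], q[, 2], q[, 1])
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("scope assignment matches a winding-number oracle", {
  flyways <- default_flyways()
  inside <- tibble::tibble(lat = 35, lon = -90)
  expect_equal(assign_scope(inside, flyways)$scope, "Mississippi")

  banded <- tibble::tibble(lat = c(37.6, 37.4), lon = -90)
  got <- assign_scope(banded, flyways, lat_band = c(32.5, 37.5))
  expect_equal(nrow(got), 1)
  expect_equal(got$lat, 37.4)

  set.seed(21)
  pts <- tibble::tibble(lat = runif(1000, 20, 55), lon = runif(1000, -135, -60))
  got <- assign_scope(pts, flyways)
  want <- rep(NA_character_, nrow(pts))
  for (i in seq_len(nrow(flyways))) {
    hit <- is.na(want) &
      oracle_winding_inside(pts$lon, pts$lat, flyways$ring[[i]])
    want[hit] <- flyways$flyway[i]
  }
  joined <- dplyr::left_join(
    pts |> dplyr::mutate(want = want),
    got |> dplyr::mutate(got = scope),
    by = c("lat", "lon")
  )
  expect_equal(joined$got, joined$want)
})

test_that("shared flyway edges go to the first canonical flyway", {
  flyways <- default_flyways()
  # lon -97 is the shared Mississippi/Central edge; Mississippi is earlier
  # in canonical order
  edge <- tibble::tibble(lat = 35, lon = -97)
  expect_equal(assign_scope(edge, flyways)$scope, "Mississippi")
})

test_that("overlapping flyway polygons are rejected", {
  sq <- function(name, x0, x1) {
    tibble::tibble(flyway = name, ring = list(rbind(
      c(x0, 30), c(x1, 30), c(x1, 40), c(x0, 40), c(x0, 30)
    )))
  }
  bad <- dplyr::bind_rows(sq("A", -100, -90), sq("B", -95, -85))
  expect_error(
    assign_scope(tibble::tibble(lat = 35, lon = -92), bad),
    "overlap"
  )
})

test_that("shift_table recovers configured displacement in the zero-noise limit", {
  cfg <- sim_config(
    seed = 2, years = 2021, species = "MALL",
    true_centroids = default_centroids("MALL", 2021, northward_km = 120),
    observers_per_cell = 15, dispersion_km = 0, presence_only_rate = 0
  )
  rows <- nonzero_observations(filter_checklists(gen_checklists(cfg))$rows)
  rows$scope <- "continental"
  st <- shift_table(rows)
  expect_equal(st$delta_km, 120, tolerance = 1e-9)
  expect_equal(st$lat_early, 34.0, tolerance = 1e-12)
  expect_equal(as.character(st$strategy), "generalist")
})

test_that("eBird-vs-GPS discrepancy is the absolute difference of signed shifts", {
  expect_equal(compare_ebird_gps(13, 19), 6)
  expect_equal(compare_ebird_gps(22, -16), 38)
  expect_equal(compare_ebird_gps(-7.5, -7.5), 0)
})
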