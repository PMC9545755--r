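test_that("identical seed and config reproduce byte-identical tables", {
  cfg <- sim_config(seed = 7, years = 2020:2021, observers_per_cell = 10,
                    violation_rates = list(travel = 0.2))
  expect_identical(gen_checklists(cfg), gen_checklists(cfg))
  expect_identical(gen_gps_fixes(cfg), gen_gps_fixes(cfg))
  expect_identical(gen_shift_dataset(cfg, 5), gen_shift_dataset(cfg, 5))
  g1 <- gen_anomaly_grid(0.3, seed = 7)
  g2 <- gen_anomaly_grid(0.3, seed = 7)
  expect_identical(g1$values, g2$values)

  other <- sim_config(seed = 8, years = 2020:2021, observers_per_cell = 10)
  expect_false(identical(gen_checklists(cfg)$lat, gen_checklists(other)$lat))
})

test_that("a missing centroid cell is a configuration error naming the cell", {
  cfg <- sim_config(
    seed = 1, years = 2020:2021, species = "MALL",
    true_centroids = default_centroids("MALL", 2020) # 2021 missing
  )
  expect_error(gen_checklists(cfg), "MALL/2021")
})

test_that("forced duration violations empty the filter output", {
  cfg <- sim_config(
    seed = 3, years = 2021, species = "MALL",
    true_centroids = default_centroids("MALL", 2021),
    observers_per_cell = 50, violation_rates = list(duration = 1.0)
  )
  rows <- gen_checklists(cfg)
  expect_equal(nrow(rows), 100)
  expect_true(all(rows$duration_h > 5))
  expect_equal(nrow(filter_checklists(rows)$rows), 0)
})

test_that("injected violation fractions follow the configured rates", {
  cfg <- sim_config(
    seed = 7, years = 2017:2021, species = c("MALL", "GADW", "SNGO", "GWFG", "NSHO"),
    true_centroids = default_centroids(
      c("MALL", "GADW", "SNGO", "GWFG", "NSHO"), 2017:2021
    ),
    observers_per_cell = 10, # 5 sp x 5 yr x 2 periods x 10 = 500 checklists
    violation_rates = list(travel = 0.2)
  )
  rows <- gen_checklists(cfg)
  expect_equal(nrow(rows), 500)
  n_viol <- sum(rows$protocol == "traveling" & rows$travel_km > 5)
  # seeded draw is reproducible ...
  expect_equal(
    n_viol,
    sum(attr(gen_checklists(cfg), "violations")$travel)
  )
  # ... and within binomial tolerance of the configured rate
  expect_lt(abs(n_viol - 100), 4 * sqrt(500 * 0.2 * 0.8))
})

test_that("GPS generator honours counts, symmetry and degenerate layouts", {
  still <- sim_config(seed = 2, gps = list(
    regions = tibble::tibble(region = "TN", n_birds = 1L,
                             center_lat = 35.5, center_lon = -88.5),
    fixes_per_bird = 12L, bird_scatter_km = 0, fix_scatter_km = 0
  ))
  fx <- gen_gps_fixes(still)
  expect_equal(nrow(fx), 12)
  c0 <- gps_centroid(fx)
  expect_equal(c(c0$lat, c0$lon), c(35.5, -88.5))

  sym <- sim_config(seed = 2, gps = list(
    regions = tibble::tibble(
      region = c("S", "N"), n_birds = c(5L, 5L),
      center_lat = c(33, 37), center_lon = c(-90, -90)
    ),
    fixes_per_bird = 10L, bird_scatter_km = 0, fix_scatter_km = 0
  ))
  pooled <- gps_centroid(gen_gps_fixes(sym), "by_region")
  expect_equal(pooled$lat, 35)

  counts <- sim_config(seed = 2, gps = list(
    regions = tibble::tibble(
      region = c("AR", "TN"), n_birds = c(3L, 7L),
      center_lat = c(34.8, 35.8), center_lon = c(-91.2, -88.9)
    ),
    fixes_per_bird = 17L
  ))
  fx <- gen_gps_fixes(counts)
  expect_equal(nrow(fx), (3 + 7) * 17)
  expect_equal(as.vector(table(fx$region)), c(3L * 17L, 7L * 17L))

  none <- sim_config(seed = 2, gps = list(
    regions = tibble::tibble(region = "AR", n_birds = 0L,
                             center_lat = 34.8, center_lon = -91.2)
  ))
  expect_warning(fx <- gen_gps_fixes(none), "No birds")
  expect_equal(nrow(fx), 0)
})

test_that("anomaly generator places the exact configured cold fraction", {
  for (f in c(0, 0.15, 0.16, 0.5)) {
    g <- gen_anomaly_grid(f, shape = c(20, 30), seed = 6)
    expect_equal(sum(g$values[g$mask] <= -4), round(f * 600))
  }
  masked <- matrix(FALSE, 10, 10)
  masked[3:7, 3:7] <- TRUE
  g <- gen_anomaly_grid(0.2, shape = c(10, 10), seed = 1, mask = masked)
  expect_equal(sum(g$values[g$mask] <= -4), round(0.2 * 25))
  expect_error(gen_anomaly_grid(0.2, mask = matrix(FALSE, 30, 60)), "mask")
})

test_that("shift dataset reduces to configured truth in the zero-noise limit", {
  cfg <- sim_config(seed = 1, years = 2019:2021, eq1_effects = list(
    beta0 = 0, strategy = c(grubbing = 0, wetland_obligate = 0),
    ece = 0, interaction = c(grubbing = 0, wetland_obligate = 0),
    sigma_year = 0, sigma_eps = 0
  ))
  d <- gen_shift_dataset(cfg, n_per_cell = 4)
  expect_true(all(d$delta_km == 0))
})

test_that("cell means converge to the generative means (law of large numbers)", {
  cfg <- sim_config(seed = 1, years = 2020:2021, eq1_effects = list(
    beta0 = 143, strategy = c(grubbing = 0, wetland_obligate = 0),
    ece = -85, interaction = c(grubbing = 0, wetland_obligate = 0),
    sigma_year = 0, sigma_eps = 30
  ))
  d <- gen_shift_dataset(cfg, n_per_cell = 200)
  means <- d |>
    dplyr::group_by(ece) |>
    dplyr::summarise(m = mean(delta_km), n = dplyr::n())
  tol <- 3 * 30 / sqrt(min(means$n))
  expect_lt(abs(means$m[!means$ece] - 143), tol)
  expect_lt(abs(means$m[means$ece] - (143 - 85)), tol)
})

test_that("year-level variance propagates into between-year cell-mean spread", {
  base <- list(
    beta0 = 100, strategy = c(grubbing = 0, wetland_obligate = 0),
    ece = 0, interaction = c(grubbing = 0, wetland_obligate = 0),
    sigma_eps = 10
  )
  v0 <- sim_config(seed = 5, years = 2010:2021,
                   eq1_effects = c(base, sigma_year = 0))
  v50 <- sim_config(seed = 5, years = 2010:2021,
                    eq1_effects = c(base, sigma_year = 50))
  spread <- function(cfg) {
    gen_shift_dataset(cfg, n_per_cell = 40) |>
      dplyr::group_by(year) |>
      dplyr::summarise(m = mean(delta_km)) |>
      dplyr::pull(m) |>
      var()
  }
  expect_gt(spread(v50), spread(v0) * 5)
})

test_that("generator probability and scale parameters are validated", {
  expect_error(sim_config(presence_only_rate = 1.2))
  expect_error(sim_config(violation_rates = list(travel = -0.1)))
  expect_error(sim_config(violation_rates = list(bogus = 0.5)), "bogus")
  expect_error(sim_config(eq1_effects = list(sigma_eps = -1)))
})
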