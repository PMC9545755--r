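# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Every generator draws from its own
# sub-stream derived from the single config seed, so tables are reproducible
# independently of generation order.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed per output table (Lehmer step keeps it < 2^31).
sub_seed <- function(seed, table) {
  offset <- match(table, c("checklists", "gps", "anomaly", "shifts"))
  as.integer((as.numeric(seed) * 48271 + offset * 7919) %% 2147483629 + 1)
}

# ~km per degree of latitude on the IUGG mean-radius sphere
KM_PER_DEG_LAT <- pi * EARTH_RADIUS_KM / 180

#' Default true centroids for the synthetic observation process
#'
#' One early and one late centroid per species, year and flyway, with a
#' configurable northward displacement between periods (wintering
#' populations drifting north late in winter). Species are offset slightly
#' from one another so their centroids are distinguishable.
#'
#' @param species Species codes.
#' @param years Study years.
#' @param flyway Flyway name, default `"Mississippi"`.
#' @param base_lat,base_lon Base early-period centroid, degrees.
#' @param northward_km True early-to-late displacement in km, recycled over
#'   species.
#' @return A tibble with columns `species`, `year`, `period`, `flyway`,
#'   `lat`, `lon`.
#' @export
default_centroids <- function(species = species_codes(), years = 2008:2021,
                              flyway = "Mississippi",
                              base_lat = 34.0, base_lon = -90.0,
                              northward_km = 120) {
  northward_km <- rep_len(northward_km, length(species))
  grid <- tidyr::expand_grid(
    species = species, year = as.integer(years), period = c("early", "late")
  )
  i <- match(grid$species, species)
  grid$flyway <- flyway
  grid$lat <- base_lat + 0.3 * (i - 1) +
    ifelse(grid$period == "late", northward_km[i] / KM_PER_DEG_LAT, 0)
  grid$lon <- base_lon + 0.2 * (i - 1)
  grid
}

#' Configuration for the synthetic-data generators
#'
#' Collects every knob of the synthetic observation process: which species
#' and years to simulate, the true centroid of each species/year/period/
#' flyway cell, per-cell checklist effort, spatial scatter, the
#' negative-binomial count model, the presence-only ("X") rate, per-rule
#' probabilities that a generated checklist violates an effort filter, the
#' linear-model effects used by [gen_shift_dataset()] and the GPS
#' deployment layout. Identical seed and configuration give byte-identical
#' tables.
#'
#' Default effect sizes are continental-scale magnitudes: a generalist
#' non-event northward shift of 143.1 km, guild offsets of +42.7 km
#' (grubbing) and -86.3 km (wetland obligate), an event main effect of
#' -84.6 km and interactions of -114.9 and +10.5 km, with year-level spread
#' of 25 km and residual spread of 100 km.
#'
#' @param seed Integer master seed; every generator derives its own
#'   sub-stream from it.
#' @param years Study years (default 2008-2021).
#' @param species Species codes from the 7-species vocabulary.
#' @param true_centroids Tibble as from [default_centroids()].
#' @param observers_per_cell Checklists generated per centroid cell.
#' @param dispersion_km Isotropic Gaussian scatter (km) of observation
#'   positions around the true centroid.
#' @param count_mean,count_size Negative-binomial mean and dispersion of
#'   observed counts (counts are `1 + rnbinom`, so every generated
#'   observation is a detection).
#' @param presence_only_rate Probability a count is recorded as "X".
#' @param violation_rates Named probabilities (names among `complete`,
#'   `travel`, `spatial_dup`, `observers`, `group_dup`, `duration`) that a
#'   checklist violates the corresponding filter rule.
#' @param eq1_effects Named list: `beta0`, `strategy` (named offsets for
#'   `grubbing` and `wetland_obligate`), `ece`, `interaction` (named as
#'   `strategy`), `sigma_year`, `sigma_eps`, all in km.
#' @param gps List describing the telemetry layout: `regions` (tibble with
#'   `region`, `n_birds`, `center_lat`, `center_lon`), `fixes_per_bird`,
#'   `cadence_h`, `bird_scatter_km`, `fix_scatter_km`, `start`.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       years = 2008:2021,
                       species = species_codes(),
                       true_centroids = default_centroids(species, years),
                       observers_per_cell = 25L,
                       dispersion_km = 50,
                       count_mean = 8,
                       count_size = 1.5,
                       presence_only_rate = 0.1,
                       violation_rates = list(),
                       eq1_effects = list(),
                       gps = list()) {
  eff <- utils::modifyList(
    list(
      beta0 = 143.1,
      strategy = c(grubbing = 42.7, wetland_obligate = -86.3),
      ece = -84.6,
      interaction = c(grubbing = -114.9, wetland_obligate = 10.5),
      sigma_year = 25,
      sigma_eps = 100
    ),
    eq1_effects
  )
  vr <- utils::modifyList(
    as.list(setNames(rep(0, length(FILTER_RULES)), FILTER_RULES)),
    as.list(violation_rates)
  )
  gps_defaults <- list(
      regions = tibble(
        region = c("AR", "TN"),
        n_birds = c(84L, 210L),
        center_lat = c(34.8, 35.8),
        center_lon = c(-91.2, -88.9)
      ),
      fixes_per_bird = 48L,
      cadence_h = 1,
      bird_scatter_km = 40,
      fix_scatter_km = 8,
      start = as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
    )
  # wholesale (non-recursive) merge: `regions` is a table, and modifyList
  # would merge it column-by-column
  gps_cfg <- gps_defaults
  gps_cfg[names(gps)] <- gps
  bad_rules <- setdiff(names(vr), FILTER_RULES)
  if (length(bad_rules) > 0) {
    abort(paste0("Unknown violation rule(s): ", paste(bad_rules, collapse = ", ")))
  }
  probs <- c(unlist(vr), presence_only_rate)
  stopifnot(
    all(probs >= 0 & probs <= 1),
    dispersion_km >= 0,
    eff$sigma_year >= 0, eff$sigma_eps >= 0,
    observers_per_cell >= 1,
    count_mean > 0, count_size > 0
  )
  structure(
    list(
      seed = as.integer(seed), years = as.integer(years), species = species,
      true_centroids = true_centroids,
      observers_per_cell = as.integer(observers_per_cell),
      dispersion_km = dispersion_km,
      count_mean = count_mean, count_size = count_size,
      presence_only_rate = presence_only_rate,
      violation_rates = vr, eq1_effects = eff, gps = gps_cfg
    ),
    class = "sim_config"
  )
}

period_dates <- function(year, period) {
  if (period == "early") {
    seq(as.Date(sprintf("%d-01-01", year)), as.Date(sprintf("%d-02-06", year)), 1)
  } else {
    seq(as.Date(sprintf("%d-02-07", year)), as.Date(sprintf("%d-02-28", year)), 1)
  }
}

# km offsets -> degrees at latitude `lat`
km_to_deg <- function(dx_km, dy_km, lat) {
  list(
    dlat = dy_km / KM_PER_DEG_LAT,
    dlon = dx_km / (KM_PER_DEG_LAT * cos(lat * pi / 180))
  )
}

#' Generate synthetic checklist observations with known truth
#'
#' For every (species, year, period, flyway) cell of the configured true
#' centroids, draws `observers_per_cell` checklists whose observation
#' positions scatter isotropically (Gaussian, scale `dispersion_km`) around
#' the cell's true centroid, with negative-binomial counts, a configurable
#' presence-only ("X") rate and per-rule injected violations of the effort
#' filters. Non-violating rows survive [filter_checklists()] untouched, so
#' downstream estimates can be compared against the configured truth.
#'
#' @param cfg A [sim_config()]. Every requested species/year combination
#'   must have centroids; a missing cell is a configuration error naming it.
#' @return A tibble of observation rows in the schema of [read_ebd()],
#'   plus `flyway` and `period` bookkeeping columns.
#' @export
gen_checklists <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cells <- dplyr::filter(
    cfg$true_centroids,
    .data$species %in% cfg$species, .data$year %in% cfg$years
  )
  want <- tidyr::expand_grid(
    species = cfg$species, year = cfg$years, period = c("early", "late")
  )
  have <- dplyr::distinct(cells, .data$species, .data$year, .data$period)
  gap <- dplyr::anti_join(want, have, by = c("species", "year", "period"))
  if (nrow(gap) > 0) {
    abort(paste0(
      "No true centroid configured for cell: ",
      gap$species[1], "/", gap$year[1], "/", gap$period[1]
    ))
  }
  with_seed(sub_seed(cfg$seed, "checklists"), {
    n_cells <- nrow(cells)
    m <- cfg$observers_per_cell
    n <- n_cells * m
    cell_of <- rep(seq_len(n_cells), each = m)
    off <- km_to_deg(
      rnorm(n, 0, cfg$dispersion_km), rnorm(n, 0, cfg$dispersion_km),
      cells$lat[cell_of]
    )
    dates <- vapply(cell_of, function(i) {
      as.integer(sample(period_dates(cells$year[i], cells$period[i]), 1))
    }, integer(1))
    x <- tibble(
      checklist_id = sprintf("S%07d", seq_len(n)),
      group_id = NA_character_,
      species = cells$species[cell_of],
      count = 1L + rnbinom(n, mu = cfg$count_mean - 1, size = cfg$count_size),
      presence_only = runif(n) < cfg$presence_only_rate,
      lat = cells$lat[cell_of] + off$dlat,
      lon = cells$lon[cell_of] + off$dlon,
      date = as.Date(dates),
      protocol = sample(c("stationary", "traveling"), n, replace = TRUE),
      travel_km = NA_real_,
      duration_h = round(runif(n, 0.2, 4.5), 2),
      n_observers = sample(1:4, n, replace = TRUE),
      complete = TRUE,
      flyway = cells$flyway[cell_of],
      period = cells$period[cell_of]
    )
    x$count[x$presence_only] <- NA_integer_
    x$travel_km[x$protocol == "traveling"] <-
      round(runif(sum(x$protocol == "traveling"), 0.1, 4.9), 2)

    vr <- cfg$violation_rates
    viol <- function(rule) runif(n) < vr[[rule]]
    v_complete <- viol("complete")
    x$complete[v_complete] <- FALSE
    v_travel <- viol("travel")
    x$protocol[v_travel] <- "traveling"
    x$travel_km[v_travel] <- round(runif(sum(v_travel), 5.01, 25), 2)
    v_obs <- viol("observers")
    x$n_observers[v_obs] <- sample(11:20, sum(v_obs), replace = TRUE)
    v_dur <- viol("duration")
    x$duration_h[v_dur] <- round(runif(sum(v_dur), 5.01, 10), 2)
    # spatial duplicates copy the position/date/species of the first row of
    # their cell (never itself): the anchor row survives deduplication
    # because it carries the smaller checklist_id
    v_sp <- viol("spatial_dup")
    anchor <- (cell_of - 1L) * m + 1L
    v_sp[anchor == seq_len(n)] <- FALSE
    x$lat[v_sp] <- x$lat[anchor[v_sp]]
    x$lon[v_sp] <- x$lon[anchor[v_sp]]
    x$date[v_sp] <- x$date[anchor[v_sp]]
    x$species[v_sp] <- x$species[anchor[v_sp]]
    # group duplicates share the anchor row's group checklist
    v_gr <- viol("group_dup")
    v_gr[anchor == seq_len(n)] <- FALSE
    gid <- sprintf("G%06d", cell_of)
    x$group_id[v_gr] <- gid[v_gr]
    x$group_id[anchor[v_gr]] <- gid[v_gr]
    attr(x, "violations") <- tibble(
      checklist_id = x$checklist_id,
      complete = v_complete, travel = v_travel, spatial_dup = v_sp,
      observers = v_obs, group_dup = v_gr, duration = v_dur
    )
    x
  })
}

#' Generate synthetic GPS telemetry fixes
#'
#' Each deployment region contributes its configured number of birds
#' (unequal by default, mirroring real marking imbalance across states);
#' each bird gets an activity center scattered around the region center and
#' a regular stream of fixes scattered around that center at the configured
#' cadence.
#'
#' @param cfg A [sim_config()]; the `gps` element controls the layout.
#' @return A tibble of fixes: `bird_id`, `timestamp`, `lat`, `lon`,
#'   `region`, plus a `truth` attribute with per-bird activity centers.
#' @export
gen_gps_fixes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- cfg$gps
  if (sum(g$regions$n_birds) == 0) {
    warn("No birds requested; returning an empty fix table.")
    return(tibble(
      bird_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      lat = double(), lon = double(), region = character()
    ))
  }
  with_seed(sub_seed(cfg$seed, "gps"), {
    birds <- tibble(
      region = rep(g$regions$region, g$regions$n_birds),
      center_lat = rep(g$regions$center_lat, g$regions$n_birds),
      center_lon = rep(g$regions$center_lon, g$regions$n_birds)
    )
    nb <- nrow(birds)
    birds$bird_id <- sprintf("%s-%04d", birds$region, seq_len(nb))
    boff <- km_to_deg(
      rnorm(nb, 0, g$bird_scatter_km), rnorm(nb, 0, g$bird_scatter_km),
      birds$center_lat
    )
    birds$lat0 <- birds$center_lat + boff$dlat
    birds$lon0 <- birds$center_lon + boff$dlon
    k <- g$fixes_per_bird
    idx <- rep(seq_len(nb), each = k)
    foff <- km_to_deg(
      rnorm(nb * k, 0, g$fix_scatter_km), rnorm(nb * k, 0, g$fix_scatter_km),
      birds$lat0[idx]
    )
    fixes <- tibble(
      bird_id = birds$bird_id[idx],
      timestamp = g$start + rep(seq_len(k) - 1, times = nb) * 3600 * g$cadence_h,
      lat = birds$lat0[idx] + foff$dlat,
      lon = birds$lon0[idx] + foff$dlon,
      region = birds$region[idx]
    )
    attr(fixes, "truth") <- birds
    fixes
  })
}

#' Generate an anomaly grid with a controlled cold-area fraction
#'
#' Builds a gridded anomaly field in which exactly
#' `round(fraction_below * n_masked)` masked cells sit at or below the
#' temperature threshold, so the severity classifier's decision is known by
#' construction.
#'
#' @param fraction_below Fraction of masked cells at or below `threshold`,
#'   in `[0, 1]`.
#' @param threshold Anomaly threshold in degrees C, default -4.
#' @param shape Grid dimensions `c(nrow, ncol)`.
#' @param seed Integer seed.
#' @param mask Optional logical matrix; default all-`TRUE`. Must have at
#'   least one `TRUE` cell.
#' @param with_area Also attach heterogeneous cell areas (km^2).
#' @return An [anomaly_grid()].
#' @export
gen_anomaly_grid <- function(fraction_below, threshold = -4,
                             shape = c(30, 60), seed = 1L,
                             mask = NULL, with_area = FALSE) {
  stopifnot(fraction_below >= 0, fraction_below <= 1)
  if (is.null(mask)) mask <- matrix(TRUE, shape[1], shape[2])
  if (!any(mask)) abort("Anomaly grid mask has no TRUE cells.")
  stopifnot(identical(dim(mask), as.integer(shape)))
  with_seed(as.integer(seed), {
    n <- prod(shape)
    values <- matrix(threshold + 1 + abs(rnorm(n)), shape[1], shape[2])
    masked_idx <- which(mask)
    k <- round(fraction_below * length(masked_idx))
    cold <- masked_idx[sample.int(length(masked_idx), k)]
    values[cold] <- threshold - abs(rnorm(k))
    area <- NULL
    if (with_area) area <- matrix(runif(n, 500, 1500), shape[1], shape[2])
    anomaly_grid(values, mask, area)
  })
}

#' Simulate shift records from the hierarchical shift model
#'
#' Draws signed early-to-late displacements from the generative form of the
#' fitted model: intercept + strategy offset + event effect + interaction +
#' a year-level random intercept + Gaussian residual noise. The true
#' parameters (including the realized year intercepts) are attached as the
#' `truth` attribute for recovery tests.
#'
#' @param cfg A [sim_config()]; effects come from `cfg$eq1_effects`.
#' @param n_per_cell Records per strategy-by-year cell.
#' @param ece_years Years in which the extreme-event indicator is `TRUE`
#'   (default 2021).
#' @return A tibble with `species`, `strategy`, `year`, `scope`, `ece`,
#'   `delta_km`.
#' @export
gen_shift_dataset <- function(cfg, n_per_cell = 10L, ece_years = 2021L) {
  stopifnot(inherits(cfg, "sim_config"))
  eff <- cfg$eq1_effects
  with_seed(sub_seed(cfg$seed, "shifts"), {
    years <- cfg$years
    alpha <- setNames(rnorm(length(years), 0, eff$sigma_year), years)
    cells <- tidyr::expand_grid(
      strategy = strategy_levels(), year = years
    )
    n <- nrow(cells) * n_per_cell
    i <- rep(seq_len(nrow(cells)), each = n_per_cell)
    strat <- cells$strategy[i]
    year <- cells$year[i]
    ece <- year %in% ece_years
    strat_off <- dplyr::coalesce(eff$strategy[strat], 0)
    int_off <- dplyr::coalesce(eff$interaction[strat], 0)
    mu <- eff$beta0 + strat_off + ece * eff$ece + ece * int_off +
      alpha[as.character(year)]
    guilds <- species_guilds()
    sp <- vapply(strat, function(s) {
      guilds$species[guilds$strategy == s][1]
    }, character(1))
    out <- tibble(
      species = sp,
      strategy = factor(strat, levels = strategy_levels()),
      year = year,
      scope = "continental",
      ece = ece,
      delta_km = mu + rnorm(n, 0, eff$sigma_eps)
    )
    attr(out, "truth") <- c(
      eff[c("beta0", "strategy", "ece", "interaction",
            "sigma_year", "sigma_eps")],
      list(alpha_year = alpha)
    )
    out
  })
}
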