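#' Great-circle distance in kilometres (haversine)
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Vectorised over all four coordinate arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS-84 assumed).
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(34, -90, 35, -90) # one degree of latitude, ~111.19 km
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  phi1 <- lat1 * rad
  phi2 <- lat2 * rad
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(a, 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Assign checklist dates to the early or late winter period
#'
#' The season is split at February 6/7: January 1 to February 6 is "early"
#' (before the mid-February weather window) and February 7 to February 28 is
#' "late". Dates outside January 1 - February 28, including February 29 in
#' leap years, are an error: they should have been dropped at ingest.
#'
#' @param date A `Date` vector (or something coercible via [as.Date()]).
#' @return A factor with levels `early`, `late`.
#' @export
#' @examples
#' assign_period(as.Date(c("2021-02-06", "2021-02-07")))
assign_period <- function(date) {
  date <- as.Date(date)
  if (anyNA(date)) abort("`date` contains missing or unparseable values.")
  m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  ok <- (m == 1L) | (m == 2L & d <= 28L)
  if (!all(ok)) {
    bad <- format(date[!ok][1])
    abort(paste0(
      "Date ", bad, " is outside the January 1 - February 28 season window."
    ))
  }
  early <- (m == 1L) | (m == 2L & d <= 6L)
  factor(ifelse(early, "early", "late"), levels = c("early", "late"))
}

# Even-odd ray-cast point-in-polygon test. `ring` is a 2-column matrix of
# (lon, lat) vertices, closed or open. Points exactly on an edge count as
# inside (assignment to the first matching flyway is resolved by the caller's
# canonical polygon order).
point_in_ring <- function(lon, lat, ring) {
  x <- ring[, 1]
  y <- ring[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) n <- n - 1L
  inside <- rep(FALSE, length(lon))
  boundary <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    boundary <- boundary | edge_hits(lon, lat, xi, yi, xj, yj)
    crosses <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | boundary
}

# TRUE where (px, py) lies exactly on the closed segment (x1,y1)-(x2,y2).
edge_hits <- function(px, py, x1, y1, x2, y2) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  within <- px >= pmin(x1, x2) & px <= pmax(x1, x2) &
    py >= pmin(y1, y2) & py <= pmax(y1, y2)
  cross == 0 & within
}

segments_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  }
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  (o1 != o2 && o3 != o4) ||
    (o1 == 0 && o2 == 0 &&
       max(min(p1[1], p2[1]), min(q1[1], q2[1])) <
         min(max(p1[1], p2[1]), max(q1[1], q2[1])) + 1e-12 &&
       max(min(p1[2], p2[2]), min(q1[2], q2[2])) <
         min(max(p1[2], p2[2]), max(q1[2], q2[2])) + 1e-12)
}

rings_overlap <- function(a, b) {
  # interiors overlap if any vertex of one is strictly inside the other,
  # or any boundary edges properly cross
  mid <- function(r) cbind((r[-nrow(r), 1] + r[-1, 1]) / 2,
                           (r[-nrow(r), 2] + r[-1, 2]) / 2)
  strictly_inside <- function(pts, ring) {
    inr <- point_in_ring(pts[, 1], pts[, 2], ring)
    one <- rep(FALSE, nrow(pts))
    for (k in which(inr)) {
      on <- FALSE
      n <- nrow(ring)
      for (i in seq_len(n - 1)) {
        if (edge_hits(pts[k, 1], pts[k, 2], ring[i, 1], ring[i, 2],
                      ring[i + 1, 1], ring[i + 1, 2])) { on <- TRUE; break }
      }
      one[k] <- !on
    }
    any(one)
  }
  if (strictly_inside(a, b) || strictly_inside(b, a)) return(TRUE)
  if (strictly_inside(mid(a), b) || strictly_inside(mid(b), a)) return(TRUE)
  FALSE
}

#' Label points with their containing flyway and optionally a latitude band
#'
#' Each point is assigned the name of the flyway polygon that contains it
#' (even-odd ray cast in geographic coordinates); points outside every
#' polygon are dropped. Points exactly on a shared boundary go to the first
#' flyway in canonical order (Atlantic, Mississippi, Central, Pacific; any
#' other names in file order after those). When `lat_band` is supplied only
#' points with `lat_band[1] <= lat <= lat_band[2]` are kept.
#'
#' @param points A data frame with `lat` and `lon` columns.
#' @param flyways Flyway polygons as returned by [read_flyways()]: a tibble
#'   with columns `flyway` and `ring` (list of 2-column lon/lat matrices).
#' @param lat_band Optional numeric length-2 latitude band, degrees N.
#' @return `points` with a `scope` column added, rows outside all polygons
#'   (or the band) removed.
#' @export
assign_scope <- function(points, flyways, lat_band = NULL) {
  stopifnot(is.data.frame(points), all(c("lat", "lon") %in% names(points)))
  canonical <- c("Atlantic", "Mississippi", "Central", "Pacific")
  ord <- order(match(flyways$flyway, canonical, nomatch = length(canonical) + 1L))
  flyways <- flyways[ord, ]
  n <- nrow(flyways)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, length.out = n - i)) {
      if (rings_overlap(flyways$ring[[i]], flyways$ring[[j]])) {
        abort(paste0(
          "Flyway polygons overlap: ", flyways$flyway[i], " and ",
          flyways$flyway[j], "."
        ))
      }
    }
  }
  if (!is.null(lat_band)) {
    stopifnot(length(lat_band) == 2)
    points <- dplyr::filter(
      points, .data$lat >= lat_band[1], .data$lat <= lat_band[2]
    )
  }
  scope <- rep(NA_character_, nrow(points))
  for (i in seq_len(n)) {
    hit <- is.na(scope) &
      point_in_ring(points$lon, points$lat, flyways$ring[[i]])
    scope[hit] <- flyways$flyway[i]
  }
  points$scope <- scope
  dplyr::filter(points, !is.na(.data$scope))
}

#' Abundance-weighted positional centroid
#'
#' The weighted arithmetic mean position in geographic degrees:
#' lat = sum(w * lat) / sum(w), and likewise for longitude. This is the
#' "center of mass" convention of centroid-based avifaunal distribution
#' studies; it is exact for data that do not straddle the antimeridian,
#' which continental North American data never do.
#'
#' @param rows Data frame with `lat`, `lon` and a weight column.
#' @param weight Name of the weight column (default `"count"`). Presence-only
#'   records (missing weight) must be resolved or dropped beforehand; see
#'   [nonzero_observations()].
#' @return A one-row tibble: `lat`, `lon`, `total_weight`, `n`.
#' @export
#' @examples
#' weighted_centroid(tibble::tibble(lat = c(34, 36), lon = -90, count = c(1, 3)))
weighted_centroid <- function(rows, weight = "count") {
  stopifnot(is.data.frame(rows), all(c("lat", "lon", weight) %in% names(rows)))
  w <- as.numeric(rows[[weight]])
  if (nrow(rows) == 0 || anyNA(w) || sum(w) <= 0) {
    abort("weighted_centroid() needs at least one row with positive, non-missing weight.")
  }
  tibble(
    lat = sum(w * rows$lat) / sum(w),
    lon = sum(w * rows$lon) / sum(w),
    total_weight = sum(w),
    n = nrow(rows)
  )
}

#' Centroid of GPS fixes, plain or region-frequency weighted
#'
#' `plain` is the unweighted mean of all fixes. `by_region` computes one
#' centroid per deployment region and averages them weighted by each
#' region's share of fixes — with weights equal to fix counts this is
#' algebraically identical to `plain`, but the weighting is exposed so other
#' weights (e.g. balanced regions) can be compared.
#'
#' @param fixes Data frame with `lat`, `lon` and (for `by_region`) `region`.
#' @param weighting `"plain"` or `"by_region"`.
#' @return A one-row tibble: `lat`, `lon`, `total_weight`, `n`.
#' @export
gps_centroid <- function(fixes, weighting = c("plain", "by_region")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(fixes), all(c("lat", "lon") %in% names(fixes)))
  if (nrow(fixes) == 0) abort("gps_centroid() needs at least one fix.")
  if (weighting == "plain") {
    return(tibble(
      lat = mean(fixes$lat), lon = mean(fixes$lon),
      total_weight = nrow(fixes), n = nrow(fixes)
    ))
  }
  stopifnot("region" %in% names(fixes))
  per <- fixes |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      lat = mean(.data$lat), lon = mean(.data$lon),
      w = dplyr::n(), .groups = "drop"
    )
  tibble(
    lat = sum(per$w * per$lat) / sum(per$w),
    lon = sum(per$w * per$lon) / sum(per$w),
    total_weight = sum(per$w),
    n = nrow(fixes)
  )
}

#' Signed early-to-late shift distance
#'
#' Magnitude is the great-circle (haversine) distance between the early and
#' late centroids; the sign encodes the north-south direction of the move:
#' positive when the late centroid lies further north, negative further
#' south, zero at equal latitude. Results are therefore read as "km shifted
#' northward".
#'
#' @param c_early,c_late One-row centroid tibbles (or anything with `lat`,
#'   `lon`).
#' @return Signed displacement in km.
#' @export
#' @examples
#' early <- tibble::tibble(lat = 34, lon = -90)
#' late <- tibble::tibble(lat = 35, lon = -90)
#' shift_distance(early, late) # +111.19 km, northward
shift_distance <- function(c_early, c_late) {
  d <- haversine_km(c_early$lat, c_early$lon, c_late$lat, c_late$lon)
  sign(c_late$lat - c_early$lat) * d
}

#' Early-to-late shift table per species, year and scope
#'
#' Groups abundance rows by species, year and scope, computes the
#' abundance-weighted centroid of each period, and returns one shift record
#' per group with both period centroids, the signed displacement and the
#' foraging strategy of the species. Groups missing either period are
#' dropped with a message.
#'
#' @param rows Filtered observation rows with positive counts, a `scope`
#'   column (see [assign_scope()]; use `scope = "continental"` for pooled
#'   data) and a `date` column.
#' @param weight Weight column name, default `"count"`.
#' @return A tibble with columns `species`, `year`, `scope`, `strategy`,
#'   `lat_early`, `lon_early`, `lat_late`, `lon_late`, `n_early`, `n_late`,
#'   `delta_km`.
#' @export
shift_table <- function(rows, weight = "count") {
  stopifnot(all(c("species", "date", "lat", "lon") %in% names(rows)))
  if (!"scope" %in% names(rows)) rows$scope <- "continental"
  rows$year <- as.integer(format(as.Date(rows$date), "%Y"))
  rows$period <- assign_period(rows$date)
  out <- rows |>
    dplyr::group_by(.data$species, .data$year, .data$scope, .data$period) |>
    dplyr::group_modify(~ weighted_centroid(.x, weight = weight)) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(
      names_from = "period",
      values_from = c("lat", "lon", "total_weight", "n"),
      names_glue = "{.value}_{period}"
    )
  if (!"lat_early" %in% names(out) || !"lat_late" %in% names(out)) {
    abort("No species/year/scope group has observations in both periods.")
  }
  complete <- !is.na(out$lat_early) & !is.na(out$lat_late)
  if (any(!complete)) {
    inform(paste0(
      sum(!complete), " species/year/scope group(s) lacked one period and were dropped."
    ))
    out <- out[complete, ]
  }
  out$delta_km <- shift_distance(
    tibble(lat = out$lat_early, lon = out$lon_early),
    tibble(lat = out$lat_late, lon = out$lon_late)
  )
  out$strategy <- factor(strategy_of(out$species), levels = strategy_levels())
  dplyr::select(
    out, "species", "year", "scope", "strategy",
    "lat_early", "lon_early", "lat_late", "lon_late",
    "n_early", "n_late", "delta_km"
  )
}

#' Absolute discrepancy between an eBird and a GPS shift estimate
#'
#' Both shifts must be signed displacements (km northward) for the same
#' species, scope and year; the discrepancy is their absolute difference.
#'
#' @param ebird_delta,gps_delta Signed shifts in km.
#' @return Non-negative km.
#' @export
#' @examples
#' compare_ebird_gps(13, 19) # 6 km apart
#' compare_ebird_gps(22, -16) # 38 km apart
compare_ebird_gps <- function(ebird_delta, gps_delta) {
  abs(ebird_delta - gps_delta)
}
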