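#' Classify a February anomaly field as severe
#'
#' A February is "severe" when temperature anomalies of `threshold` degrees C
#' or colder cover strictly more than `fraction` of the masked region
#' (the conterminous US in the motivating analysis). Coverage is the share
#' of masked cells meeting the threshold, area-weighted when the grid
#' carries cell areas. Both boundaries are literal: anomalies `<= threshold`
#' count, and the covered fraction must be `> fraction`.
#'
#' @param grid An [anomaly_grid()].
#' @param threshold Anomaly threshold in degrees C, default -4.
#' @param fraction Required areal fraction, default 0.15.
#' @return `TRUE` if severe, `FALSE` otherwise.
#' @export
#' @examples
#' g <- gen_anomaly_grid(fraction_below = 0.16, seed = 1)
#' classify_severe_february(g)
classify_severe_february <- function(grid, threshold = -4, fraction = 0.15) {
  stopifnot(inherits(grid, "anomaly_grid"))
  v <- grid$values[grid$mask]
  cold <- v <= threshold
  frac <- if (is.null(grid$cell_area)) {
    mean(cold)
  } else {
    a <- grid$cell_area[grid$mask]
    sum(a[cold]) / sum(a)
  }
  frac > fraction
}

#' Year labels for the two analysis designs
#'
#' Builds the per-year labels driving the two analyses: `severe_feb` flags
#' years whose February met the severity criterion; `in_ece_design` is
#' `FALSE` for 2015 and 2019, which are excluded from the single-event
#' analysis because those Februarys were also abnormally cold; `ece_2021`
#' is `TRUE` only for 2021, the polar-vortex event year.
#'
#' @param years Integer vector of study years.
#' @param severe_years Years classified as severe Februarys; default
#'   `c(2015, 2019, 2021)`.
#' @return A tibble with columns `year`, `severe_feb`, `in_ece_design`,
#'   `ece_2021`.
#' @export
#' @examples
#' year_labels(2008:2021)
year_labels <- function(years, severe_years = c(2015L, 2019L, 2021L)) {
  years <- as.integer(years)
  tibble(
    year = years,
    severe_feb = years %in% severe_years,
    in_ece_design = !(years %in% c(2015L, 2019L)),
    ece_2021 = years == 2021L
  )
}

#' Build a model-ready design table from shift records and year labels
#'
#' Two designs are supported. `"ece2021"` isolates the February 2021 event:
#' years 2015 and 2019 are removed (their Februarys were also abnormally
#' cold) and the event indicator `ece` is `TRUE` only for 2021; this design
#' may be fit per flyway or continentally. `"severe_feb"` pools all severe
#' Februarys: every year is kept, `ece` follows `severe_feb`, and the
#' design is continental-scope only (severe cold occurred at different
#' spatial scales in the different severe years, so flyway-specific fits
#' are not built). Labeling never alters `delta_km`.
#'
#' @param shifts A shift-record tibble (see [shift_table()] or
#'   [gen_shift_dataset()]) with at least `year`, `strategy`, `delta_km`
#'   and optionally `scope`.
#' @param labels A [year_labels()] tibble covering every year in `shifts`.
#' @param analysis `"ece2021"` or `"severe_feb"`.
#' @return The subset of `shifts` with a logical `ece` column added.
#' @export
build_design <- function(shifts, labels, analysis = c("ece2021", "severe_feb")) {
  analysis <- match.arg(analysis)
  missing_years <- setdiff(unique(shifts$year), labels$year)
  if (length(missing_years) > 0) {
    abort(paste0(
      "No year label for year(s): ", paste(sort(missing_years), collapse = ", ")
    ))
  }
  x <- dplyr::left_join(shifts, labels, by = "year")
  if (analysis == "ece2021") {
    x <- dplyr::filter(x, .data$in_ece_design)
    x$ece <- x$ece_2021
  } else {
    if ("scope" %in% names(x)) {
      x <- dplyr::filter(x, .data$scope == "continental")
    }
    x$ece <- x$severe_feb
  }
  dplyr::select(x, -"severe_feb", -"in_ece_design", -"ece_2021")
}
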