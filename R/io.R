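# Column maps for the two accepted checklist dialects: the raw eBird Basic
# Dataset (EBD) header names, and the simplified lowercase schema written by
# the synthetic-data generator.
EBD_RAW_COLS <- c(
  checklist_id = "SAMPLING EVENT IDENTIFIER",
  group_id     = "GROUP IDENTIFIER",
  species      = "COMMON NAME",
  count        = "OBSERVATION COUNT",
  lat          = "LATITUDE",
  lon          = "LONGITUDE",
  date         = "OBSERVATION DATE",
  protocol     = "PROTOCOL TYPE",
  travel_km    = "EFFORT DISTANCE KM",
  duration_min = "DURATION MINUTES",
  n_observers  = "NUMBER OBSERVERS",
  complete     = "ALL SPECIES REPORTED"
)

EBD_SIMPLE_COLS <- c(
  checklist_id = "checklist_id", group_id = "group_id", species = "species",
  count = "count", lat = "lat", lon = "lon", date = "date",
  protocol = "protocol", travel_km = "travel_km", duration_h = "duration_h",
  n_observers = "n_observers", complete = "complete"
)

#' Read an eBird Basic Dataset-style checklist file
#'
#' Accepts tab-delimited files with either raw EBD header names
#' (`SAMPLING EVENT IDENTIFIER`, `COMMON NAME`, `OBSERVATION COUNT`, ...,
#' with durations in minutes and species as common names) or the simplified
#' lowercase schema written by [write_ebd()] (species as 4-letter codes,
#' durations in hours). On ingest, rows dated outside January 1 -
#' February 28 of any year (including February 29) are dropped, durations
#' are converted to hours, presence-only counts (`"X"`) become `NA` counts
#' with `presence_only = TRUE`, and rows for species outside the 7-species
#' vocabulary are dropped with a message giving the count.
#'
#' @param path Path to a tab-delimited UTF-8 file with a header row.
#' @param season_window Two `Date`-coercible month-day bounds applied within
#'   every year, default `c("01-01", "02-28")`.
#' @return A tibble of observation rows: `checklist_id`, `group_id`,
#'   `species`, `count`, `presence_only`, `lat`, `lon`, `date`, `protocol`,
#'   `travel_km`, `duration_h`, `n_observers`, `complete`.
#' @export
read_ebd <- function(path, season_window = c("01-01", "02-28")) {
  raw <- readr::read_tsv(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  dialect <- if (all(EBD_RAW_COLS %in% names(raw))) {
    "raw"
  } else if (all(EBD_SIMPLE_COLS %in% names(raw))) {
    "simple"
  } else {
    missing_raw <- setdiff(EBD_RAW_COLS, names(raw))
    missing_simple <- setdiff(EBD_SIMPLE_COLS, names(raw))
    miss <- if (length(missing_simple) <= length(missing_raw)) {
      missing_simple
    } else {
      missing_raw
    }
    abort(paste0(
      "Checklist file matches neither EBD dialect; missing column(s): ",
      paste(miss, collapse = ", ")
    ))
  }
  cols <- if (dialect == "raw") EBD_RAW_COLS else EBD_SIMPLE_COLS
  x <- tibble(
    checklist_id = raw[[cols[["checklist_id"]]]],
    group_id = na_if_blank(raw[[cols[["group_id"]]]]),
    species_in = raw[[cols[["species"]]]],
    count_raw = raw[[cols[["count"]]]],
    lat = suppressWarnings(as.numeric(raw[[cols[["lat"]]]])),
    lon = suppressWarnings(as.numeric(raw[[cols[["lon"]]]])),
    date = suppressWarnings(as.Date(raw[[cols[["date"]]]])),
    protocol_in = raw[[cols[["protocol"]]]],
    travel_km = suppressWarnings(as.numeric(raw[[cols[["travel_km"]]]])),
    n_observers = suppressWarnings(as.integer(raw[[cols[["n_observers"]]]])),
    complete = parse_flag(raw[[cols[["complete"]]]])
  )
  x$duration_h <- if (dialect == "raw") {
    suppressWarnings(as.numeric(raw[[cols[["duration_min"]]]])) / 60
  } else {
    suppressWarnings(as.numeric(raw[[cols[["duration_h"]]]]))
  }
  x$species <- if (dialect == "raw") {
    g <- species_guilds()
    g$species[match(x$species_in, g$common_name)]
  } else {
    ifelse(x$species_in %in% species_codes(), x$species_in, NA_character_)
  }

  bad_parse <- is.na(x$checklist_id) | is.na(x$lat) | is.na(x$lon) |
    is.na(x$date) | abs(x$lat) > 90 | abs(x$lon) > 180
  if (any(bad_parse)) {
    inform(paste0(sum(bad_parse), " unparseable row(s) skipped."))
    x <- x[!bad_parse, ]
  }
  unknown <- is.na(x$species)
  if (any(unknown)) {
    inform(paste0(sum(unknown), " row(s) with unknown species dropped."))
    x <- x[!unknown, ]
  }
  md <- format(x$date, "%m-%d")
  in_window <- md >= season_window[1] & md <= season_window[2]
  x <- x[in_window, ]

  x$presence_only <- x$count_raw %in% c("X", "x")
  x$count <- suppressWarnings(as.integer(x$count_raw))
  x$count[x$presence_only] <- NA_integer_
  x$protocol <- dplyr::case_match(
    tolower(x$protocol_in),
    c("stationary", "ebird - stationary count") ~ "stationary",
    c("traveling", "travelling", "ebird - traveling count") ~ "traveling",
    .default = "other"
  )
  dplyr::select(
    x, "checklist_id", "group_id", "species", "count", "presence_only",
    "lat", "lon", "date", "protocol", "travel_km", "duration_h",
    "n_observers", "complete"
  )
}

na_if_blank <- function(x) {
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

parse_flag <- function(x) {
  tolower(x) %in% c("1", "true", "t", "yes")
}

#' Write observation rows in the simplified EBD dialect
#'
#' Tab-separated UTF-8 with the lowercase schema read back by [read_ebd()];
#' presence-only records are written as count `"X"`.
#'
#' @param rows A tibble as returned by [read_ebd()] or [gen_checklists()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ebd <- function(rows, path) {
  out <- tibble(
    checklist_id = rows$checklist_id,
    group_id = rows$group_id %||% NA_character_,
    species = rows$species,
    count = ifelse(rows$presence_only, "X", as.character(rows$count)),
    lat = rows$lat, lon = rows$lon, date = format(rows$date, "%Y-%m-%d"),
    protocol = rows$protocol, travel_km = rows$travel_km,
    duration_h = rows$duration_h, n_observers = rows$n_observers,
    complete = rows$complete
  )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read / write GPS telemetry fixes
#'
#' CSV with columns `bird_id`, `timestamp` (UTC instant, ISO 8601), `lat`,
#' `lon`, `region`. Timestamps must be strictly increasing within each bird
#' and regions non-empty.
#'
#' @param path File path.
#' @return A tibble of fixes.
#' @export
read_gps <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      bird_id = readr::col_character(),
      timestamp = readr::col_datetime(),
      lat = readr::col_double(),
      lon = readr::col_double(),
      region = readr::col_character()
    ),
    progress = FALSE
  )
  if (any(is.na(x$region) | x$region == "")) {
    abort("GPS fixes must carry a non-empty deployment region.")
  }
  bad <- x |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$timestamp, strictly = TRUE),
                     .groups = "drop")
  if (any(!bad$ok)) {
    abort(paste0(
      "Timestamps not strictly increasing for bird(s): ",
      paste(bad$bird_id[!bad$ok], collapse = ", ")
    ))
  }
  x
}

#' @rdname read_gps
#' @param fixes A tibble of fixes.
#' @export
write_gps <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write flyway polygons as GeoJSON
#'
#' A FeatureCollection of Polygon features in geographic (WGS-84) degrees;
#' each feature must carry a `flyway` name property. Only single-ring
#' polygons are supported (administrative flyway boundaries have no holes).
#'
#' @param path File path.
#' @return A tibble with columns `flyway` and `ring` (list of closed
#'   2-column lon/lat matrices).
#' @export
read_flyways <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    abort("Flyway file must be a GeoJSON FeatureCollection.")
  }
  crs_name <- tryCatch(gj$crs$properties$name, error = function(e) NULL)
  if (!is.null(crs_name) &&
      !grepl("CRS84|4326", crs_name, ignore.case = TRUE)) {
    abort(paste0("Unsupported CRS: ", crs_name, " (geographic lat-lon required)."))
  }
  feats <- purrr::map(gj$features, function(f) {
    name <- f$properties$flyway
    if (is.null(name) || !nzchar(name)) {
      abort("Every flyway feature needs a non-empty 'flyway' name property.")
    }
    if (!identical(f$geometry$type, "Polygon")) {
      abort(paste0("Flyway '", name, "': only Polygon geometries are supported."))
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, purrr::map(ring, ~ c(.x[[1]], .x[[2]])))
    if (nrow(m) < 4 || !all(m[1, ] == m[nrow(m), ])) {
      abort(paste0("Flyway '", name, "': ring must be closed with >= 4 vertices."))
    }
    if (any(abs(m[, 2]) > 90) || any(abs(m[, 1]) > 180)) {
      abort(paste0("Flyway '", name, "': coordinates outside geographic bounds."))
    }
    tibble(flyway = name, ring = list(m))
  })
  dplyr::bind_rows(feats)
}

#' @rdname read_flyways
#' @param flyways A tibble as returned by [read_flyways()].
#' @export
write_flyways <- function(flyways, path) {
  features <- purrr::map2(flyways$flyway, flyways$ring, function(name, ring) {
    coords <- purrr::map(seq_len(nrow(ring)), ~ list(ring[.x, 1], ring[.x, 2]))
    list(
      type = "Feature",
      properties = list(flyway = name),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Construct a gridded temperature-anomaly field
#'
#' @param values Numeric matrix of anomalies in degrees C.
#' @param mask Logical matrix of the same shape, `TRUE` over the region of
#'   interest (e.g. the conterminous US); must contain at least one `TRUE`.
#' @param cell_area Optional numeric matrix of cell areas (km^2) used for
#'   area-weighted classification.
#' @return An `anomaly_grid` object.
#' @export
anomaly_grid <- function(values, mask, cell_area = NULL) {
  stopifnot(is.matrix(values), is.matrix(mask),
            identical(dim(values), dim(mask)))
  mask <- mask & !is.na(mask)
  if (!any(mask)) abort("Anomaly grid mask has no TRUE cells.")
  if (!is.null(cell_area)) {
    stopifnot(is.matrix(cell_area), identical(dim(cell_area), dim(values)),
              all(cell_area >= 0))
  }
  structure(
    list(values = values, mask = mask, cell_area = cell_area),
    class = "anomaly_grid"
  )
}

#' @export
print.anomaly_grid <- function(x, ...) {
  cat(sprintf(
    "<anomaly_grid> %d x %d cells, %d masked, range [%.2f, %.2f] degC%s\n",
    nrow(x$values), ncol(x$values), sum(x$mask),
    min(x$values[x$mask]), max(x$values[x$mask]),
    if (is.null(x$cell_area)) "" else ", area-weighted"
  ))
  invisible(x)
}

#' Read / write anomaly grids as long-format CSV
#'
#' Plain-text exchange format: columns `row`, `col`, `value`, `mask` and
#' optionally `cell_area`, one line per grid cell, dimensions implied by the
#' index ranges.
#'
#' @param path File path.
#' @return An `anomaly_grid` object.
#' @export
read_anomaly <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      row = readr::col_integer(), col = readr::col_integer(),
      value = readr::col_double(), mask = readr::col_logical(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  nr <- max(x$row); nc <- max(x$col)
  if (nrow(x) != nr * nc) abort("Anomaly grid file does not cover a full grid.")
  idx <- cbind(x$row, x$col)
  values <- matrix(NA_real_, nr, nc); values[idx] <- x$value
  mask <- matrix(FALSE, nr, nc); mask[idx] <- x$mask
  cell_area <- NULL
  if ("cell_area" %in% names(x)) {
    cell_area <- matrix(NA_real_, nr, nc); cell_area[idx] <- x$cell_area
  }
  anomaly_grid(values, mask, cell_area)
}

#' @rdname read_anomaly
#' @param grid An `anomaly_grid`.
#' @export
write_anomaly <- function(grid, path) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  out <- tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    value = as.vector(grid$values),
    mask = as.vector(grid$mask)
  )
  if (!is.null(grid$cell_area)) out$cell_area <- as.vector(grid$cell_area)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
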