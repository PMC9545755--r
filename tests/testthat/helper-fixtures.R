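# Builders for small in-code fixtures.

obs_row <- function(checklist_id = "S1", group_id = NA_character_,
                    species = "MALL", count = 5L, presence_only = FALSE,
                    lat = 35, lon = -89, date = as.Date("2021-01-15"),
                    protocol = "stationary", travel_km = NA_real_,
                    duration_h = 1, n_observers = 2L, complete = TRUE) {
  tibble::tibble(
    checklist_id = checklist_id, group_id = group_id, species = species,
    count = as.integer(count), presence_only = presence_only,
    lat = lat, lon = lon, date = date, protocol = protocol,
    travel_km = travel_km, duration_h = duration_h,
    n_observers = as.integer(n_observers), complete = complete
  )
}

# Independent per-predicate application of the six filter rules, used as
# the brute-force oracle for the surviving set (ignores the per-rule
# attrition order, which the report tests cover separately).
oracle_surviving_ids <- function(rows, dedupe_by = "species") {
  x <- rows[rows$complete, ]
  x <- x[x$protocol == "stationary" |
           (x$protocol == "traveling" & !is.na(x$travel_km) & x$travel_km < 5), ]
  key <- if (dedupe_by == "species") {
    paste(x$lat, x$lon, x$date, x$species)
  } else {
    paste(x$lat, x$lon, x$date)
  }
  keep <- rep(FALSE, nrow(x))
  for (k in unique(key)) {
    idx <- which(key == k)
    ids <- x$checklist_id[idx]
    keep[idx[ids == min(ids)][1]] <- TRUE
  }
  x <- x[keep, ]
  x <- x[x$n_observers <= 10, ]
  gid <- x$group_id
  drop <- rep(FALSE, nrow(x))
  for (g in unique(gid[!is.na(gid)])) {
    idx <- which(!is.na(gid) & gid == g)
    best <- min(x$checklist_id[idx])
    drop[idx[x$checklist_id[idx] != best]] <- TRUE
  }
  x <- x[!drop, ]
  x <- x[is.na(x$duration_h) | x$duration_h <= 5, ]
  sort(paste(x$checklist_id, x$species, x$lat))
}
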