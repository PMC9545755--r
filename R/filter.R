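# The six effort-filtering rules in application order. Each is a pure
# predicate except the two deduplication rules, whose tie-break keeps the
# lexicographically smallest checklist_id (deterministic and independent of
# input order).
FILTER_RULES <- c(
  "complete", "travel", "spatial_dup", "observers", "group_dup", "duration"
)

#' Semi-structured effort filtering of checklist observations
#'
#' Applies, in order, the standard effort filters for semi-structured
#' citizen-science checklists: (1) keep only complete checklists; (2) keep
#' stationary protocols, or traveling protocols with travel distance
#' strictly under 5 km; (3) keep one observation per unique
#' (latitude, longitude, date, species) combination so heavily surveyed
#' sites are not over-represented; (4) drop checklists with more than 10
#' observers; (5) drop duplicate checklists, keeping one per shared group
#' identifier; (6) keep checklists of at most 5 h duration. Boundary
#' semantics are literal: travel `< 5` km, observers `<= 10`, duration
#' `<= 5` h. A traveling checklist with missing travel distance fails (2)
#' (the bound cannot be verified); a missing duration passes (6). The
#' deduplication tie-break for (3) and (5) keeps the row with the smallest
#' `checklist_id`.
#'
#' @param rows Observation rows as returned by [read_ebd()].
#' @param dedupe_by For rule (3): `"species"` (default) deduplicates
#'   per species-row on (lat, lon, date, species); `"checklist"`
#'   deduplicates on (lat, lon, date) across species.
#' @return A list with elements `rows` (the surviving tibble) and `report`,
#'   a tibble of per-rule attrition in application order with attributes
#'   `n_input` and `n_output` (so `n_input - sum(removed) = n_output`).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' filtered <- filter_checklists(gen_checklists(cfg))
#' filtered$report
filter_checklists <- function(rows, dedupe_by = c("species", "checklist")) {
  dedupe_by <- match.arg(dedupe_by)
  n_in <- nrow(rows)
  removed <- setNames(integer(length(FILTER_RULES)), FILTER_RULES)

  keep_stage <- function(x, keep, rule) {
    removed[[rule]] <<- nrow(x) - sum(keep)
    x[keep, ]
  }

  x <- keep_stage(rows, rows$complete %in% TRUE, "complete")
  x <- keep_stage(
    x,
    x$protocol == "stationary" |
      (x$protocol == "traveling" & !is.na(x$travel_km) & x$travel_km < 5),
    "travel"
  )
  key <- if (dedupe_by == "species") {
    paste(x$lat, x$lon, x$date, x$species, sep = "\r")
  } else {
    paste(x$lat, x$lon, x$date, sep = "\r")
  }
  x <- keep_stage(x, first_by_id(key, x$checklist_id), "spatial_dup")
  x <- keep_stage(x, x$n_observers <= 10, "observers")
  gkey <- ifelse(is.na(x$group_id), paste0("\rsolo\r", x$checklist_id), x$group_id)
  x <- keep_stage(x, group_rep(gkey, x$checklist_id), "group_dup")
  x <- keep_stage(x, is.na(x$duration_h) | x$duration_h <= 5, "duration")

  report <- tibble(
    rule = FILTER_RULES,
    removed = as.integer(removed)
  )
  attr(report, "n_input") <- n_in
  attr(report, "n_output") <- nrow(x)
  list(rows = x, report = report)
}

# TRUE for the row with the smallest id within each key (rule 3 tie-break).
first_by_id <- function(key, id) {
  ord <- order(key, id)
  k <- key[ord]
  first <- c(TRUE, k[-1] != k[-length(k)])
  out <- logical(length(key))
  out[ord] <- first
  out
}

# Rule 5: within a group, keep every row of the checklist with the smallest
# id; checklists not in a group keep themselves (their key is unique).
group_rep <- function(gkey, id) {
  if (length(id) == 0) return(logical(0))
  min_id <- tapply(id, gkey, min)
  id == unname(min_id[gkey])
}

#' Keep only positive-abundance observations
#'
#' Distribution centroids are weighted by abundance, so zero counts carry no
#' weight and are dropped. Presence-only records (count recorded as "X")
#' cannot contribute an abundance weight and are dropped by default; set
#' `presence_as_one = TRUE` to recode them as count 1.
#'
#' @param rows Filtered observation rows.
#' @param presence_as_one Recode presence-only records as count 1 instead of
#'   dropping them.
#' @return Rows with resolved `count >= 1`.
#' @export
nonzero_observations <- function(rows, presence_as_one = FALSE) {
  if (presence_as_one) {
    rows$count[rows$presence_only] <- 1L
    rows$presence_only <- FALSE
  }
  dplyr::filter(rows, !.data$presence_only, !is.na(.data$count), .data$count >= 1)
}
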