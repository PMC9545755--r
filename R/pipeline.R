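#' Synthetic administrative flyway polygons
#'
#' Four non-overlapping longitude-band rectangles standing in for the
#' Atlantic, Mississippi, Central and Pacific administrative flyways.
#' These are synthetic simplifications for simulation and testing, not the
#' real administrative boundaries.
#'
#' @param lat_range Latitude extent of every band, degrees N.
#' @return A flyway tibble in the format of [read_flyways()].
#' @export
default_flyways <- function(lat_range = c(24, 50)) {
  bands <- list(
    Atlantic = c(-82, -65),
    Mississippi = c(-97, -82),
    Central = c(-110, -97),
    Pacific = c(-130, -110)
  )
  dplyr::bind_rows(purrr::imap(bands, function(lon, name) {
    ring <- rbind(
      c(lon[1], lat_range[1]), c(lon[2], lat_range[1]),
      c(lon[2], lat_range[2]), c(lon[1], lat_range[2]),
      c(lon[1], lat_range[1])
    )
    tibble(flyway = name, ring = list(ring))
  }))
}

#' Default pipeline configuration
#'
#' @param seed Master seed for every stage.
#' @param out_dir Directory for all stage outputs.
#' @param analysis `"ece2021"` or `"severe_feb"`.
#' @param scope Which scope's shift records the model is fit to: a flyway
#'   name or `"continental"` (default).
#' @param years Study years.
#' @param severe_years Years whose February met the severity criterion
#'   (historical labels are inputs, not computed claims; the bundled
#'   anomaly stage demonstrates the criterion on a simulated grid).
#' @param lat_band Optional latitude band, e.g. `c(32.5, 37.5)`.
#' @param flyways_file Optional GeoJSON path; when `NULL` the synthetic
#'   [default_flyways()] are written and used.
#' @param sim Named list of overrides passed to [sim_config()].
#' @param model Named list of overrides passed to [shift_model_spec()].
#' @return A named list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("driftshift-run-"),
                            analysis = "ece2021", scope = "continental",
                            years = 2008:2021,
                            severe_years = c(2015L, 2019L, 2021L),
                            lat_band = NULL, flyways_file = NULL,
                            sim = list(), model = list()) {
  list(
    seed = as.integer(seed), out_dir = out_dir, analysis = analysis,
    scope = scope, years = as.integer(years),
    severe_years = as.integer(severe_years),
    lat_band = lat_band, flyways_file = flyways_file,
    sim = sim, model = model
  )
}

#' Run the full simulate-to-report pipeline
#'
#' Executes the six stages — simulate, filter, centroids, classify, fit,
#' report — from a single configuration (a list from [pipeline_config()],
#' or a path to a YAML file with the same fields). Every stage writes its
#' artifact under `out_dir` and is recorded in a JSON manifest with an MD5
#' content hash, the seed and the package version, so a rerun with the same
#' configuration reproduces all non-MCMC artifacts byte-identically. Any
#' stage failure aborts naming the stage and cause.
#'
#' @param config A list or a YAML file path.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_config()
  config <- utils::modifyList(defaults, config)
  if (!is.null(config$flyways_file) && !file.exists(config$flyways_file)) {
    abort(paste0("Flyway file not found: ", config$flyways_file))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("driftshift")),
    stages = list()
  )
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      stage = stage,
      outputs = as.list(setNames(
        unname(tools::md5sum(files)), basename(files)
      ))
    )
  }
  run_stage <- function(stage, code) {
    tryCatch(force(code), error = function(e) {
      abort(paste0("Stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  sim_args <- utils::modifyList(
    list(seed = config$seed, years = config$years), config$sim
  )
  run_stage("simulate", {
    cfg <- do.call(sim_config, sim_args)
    write_ebd(gen_checklists(cfg), p("ebd.tsv"))
    write_gps(gen_gps_fixes(cfg), p("gps.csv"))
    write_anomaly(
      gen_anomaly_grid(fraction_below = 0.16, seed = cfg$seed),
      p("anomaly.csv")
    )
    if (is.null(config$flyways_file)) {
      write_flyways(default_flyways(), p("flyways.geojson"))
      config$flyways_file <- p("flyways.geojson")
    }
    record("simulate", c(p("ebd.tsv"), p("gps.csv"), p("anomaly.csv"),
                         config$flyways_file))
  })

  run_stage("filter", {
    obs <- read_ebd(p("ebd.tsv"))
    filtered <- filter_checklists(obs)
    kept <- nonzero_observations(filtered$rows)
    write_ebd(kept, p("filtered.tsv"))
    jsonlite::write_json(
      list(
        n_input = attr(filtered$report, "n_input"),
        n_output = attr(filtered$report, "n_output"),
        n_positive = nrow(kept),
        removed = setNames(
          as.list(filtered$report$removed), filtered$report$rule
        )
      ),
      p("filter_report.json"), auto_unbox = TRUE
    )
    record("filter", c(p("filtered.tsv"), p("filter_report.json")))
  })

  shifts <- run_stage("centroids", {
    kept <- read_ebd(p("filtered.tsv"))
    flyways <- read_flyways(config$flyways_file)
    scoped <- assign_scope(kept, flyways, lat_band = config$lat_band)
    continental <- dplyr::mutate(kept, scope = "continental")
    shifts <- dplyr::bind_rows(shift_table(scoped), shift_table(continental))
    readr::write_csv(shifts, p("shifts.csv"), progress = FALSE)
    record("centroids", p("shifts.csv"))
    shifts
  })

  labels <- run_stage("classify", {
    grid <- read_anomaly(p("anomaly.csv"))
    grid_severe <- classify_severe_february(grid)
    labels <- year_labels(config$years, severe_years = config$severe_years)
    jsonlite::write_json(
      list(
        simulated_grid_severe = grid_severe,
        years = purrr::transpose(as.list(labels))
      ),
      p("labels.json"), auto_unbox = TRUE
    )
    record("classify", p("labels.json"))
    labels
  })

  fit <- run_stage("fit", {
    in_scope <- dplyr::filter(shifts, .data$scope == config$scope)
    design <- build_design(in_scope, labels, analysis = config$analysis)
    model_args <- utils::modifyList(
      list(seed = config$seed), config$model
    )
    spec <- do.call(shift_model_spec, model_args)
    fit <- fit_shift_model(design, spec)
    readr::write_csv(tidy(fit), p("posterior_summary.csv"), progress = FALSE)
    record("fit", p("posterior_summary.csv"))
    fit
  })

  run_stage("report", {
    cells <- marginal_medians(fit)
    readr::write_csv(as_tibble(cells), p("cells.csv"), progress = FALSE)
    record("report", p("cells.csv"))
  })

  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  inform(paste0(
    "Pipeline complete: ", length(manifest$stages), " stages written to ",
    config$out_dir
  ))
  invisible(manifest)
}
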