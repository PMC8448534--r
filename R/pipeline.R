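# End-to-end pipeline: ingest or simulate an OD dataset, fit the requested
# model variants, and produce ranking and accuracy reports. Outputs are a
# pure function of (inputs, configuration, seed).

#' Pipeline configuration
#'
#' Either point `districts`/`trips` at CSV files in the package's standard
#' formats, or leave them `NULL` to simulate one of the benchmark scenarios.
#'
#' @param districts,trips Paths to the district table and trip matrix CSVs,
#'   or `NULL` to simulate.
#' @param scenario Benchmark scenario to simulate when no files are given:
#'   `"basic"`, `"regional_urbanicity"` or `"radiation"`.
#' @param models Model variants to fit; any of `"basic"`, `"urbanicity"`,
#'   `"regional"`, `"regional_urbanicity"`, `"radiation"`.
#' @param kernel Distance kernel for the gravity fits.
#' @param urban_threshold Urbanicity threshold (0.5 conventional, 0.1 for
#'   sensitivity analyses).
#' @param margin Accuracy margin for the evaluation report.
#' @param control An [mcmc_control()]; per-model seeds are derived from
#'   `seed`, overriding `control$seed`.
#' @param config A [scenario_config()] for simulation.
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param seed Master seed for the run.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(districts = NULL, trips = NULL, scenario = "basic",
                       models = c("basic", "urbanicity", "regional",
                                  "regional_urbanicity", "radiation"),
                       kernel = c("power", "exponential"),
                       urban_threshold = 0.5, margin = 0.10,
                       control = mcmc_control(), config = scenario_config(),
                       outdir = NULL, seed = 1L) {
  kernel <- match.arg(kernel)
  models <- match.arg(models, several.ok = TRUE)
  if (length(models) < 1L) stop("at least one model variant is required", call. = FALSE)
  if (urban_threshold < 0 || urban_threshold > 1)
    stop("urban_threshold must be in [0, 1]", call. = FALSE)
  scenario <- match.arg(scenario, c("basic", "regional_urbanicity", "radiation"))
  structure(list(districts = districts, trips = trips, scenario = scenario,
                 models = models, kernel = kernel,
                 urban_threshold = urban_threshold, margin = margin,
                 control = control, config = config, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `control` and
#' `config` may be nested maps with the respective constructor's keys.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$control))
    y$control <- do.call(mcmc_control,
                         y$control[intersect(names(y$control), names(formals(mcmc_control)))])
  if (!is.null(y$config)) {
    if (!is.null(y$config$bbox)) y$config$bbox <- unlist(y$config$bbox)
    y$config <- do.call(scenario_config,
                        y$config[intersect(names(y$config), names(formals(scenario_config)))])
  }
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

#' Run the full modelling pipeline
#'
#' Loads (or simulates) a district table and observed trip matrix, drops
#' districts with no trip data, rounds non-integer counts, fits every
#' requested model variant, and assembles the DIC ranking and trip-type
#' accuracy report. When `outdir` is set, writes chain CSVs and metadata per
#' fit, the evaluation tables, the (simulated) input data, and a run log
#' recording seed, package version, dropped districts and rounding events.
#'
#' @param config A [run_config()] or the path to its YAML file.
#' @return Invisibly, a list with `fits`, `report`, `geography`, `trips`,
#'   `typology`, `dropped`, `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log <- c(sprintf("odflow %s on R %s.%s",
                   as.character(utils::packageVersion("odflow")),
                   R.version$major, R.version$minor),
           sprintf("seed: %d", config$seed),
           sprintf("models: %s", paste(config$models, collapse = ", ")),
           sprintf("kernel: %s; urban threshold: %g", config$kernel,
                   config$urban_threshold))
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log <<- c(log, msg)
  }

  simulated <- is.null(config$districts) || is.null(config$trips)
  if (simulated) {
    note("simulating scenario '%s'", config$scenario)
    suite <- make_benchmark_suite(config$seed, config$config)
    sc <- suite[[config$scenario]]
    geo <- sc$geography
    trips <- sc$trips
  } else {
    note("reading districts from %s", config$districts)
    dd <- read_districts(config$districts)
    geo <- geography(dd, config$urban_threshold)
    note("reading trips from %s", config$trips)
    trips <- tryCatch(read_trips(config$trips, ids = geo$districts$id),
                      error = function(e)
                        stop("trip matrix is inconsistent with the district table: ",
                             conditionMessage(e), call. = FALSE))
  }
  prep <- drop_missing_districts(trips, geo)
  if (length(prep$dropped))
    log <- c(log, sprintf("dropped districts with no trip data: %s",
                          paste(prep$dropped, collapse = ", ")))
  geo <- prep$geography
  trips <- prep$trips
  off <- which(row(trips) != col(trips) & !is.na(trips))
  n_round <- sum(trips[off] != round(trips[off]))
  if (n_round > 0)
    log <- c(log, sprintf("rounded %d non-integer observed counts", n_round))
  trips <- suppressMessages(.round_counts(trips))
  typ <- trip_typology(geo)

  fits <- list()
  for (i in seq_along(config$models)) {
    mdl <- config$models[i]
    ctl <- config$control
    ctl$seed <- config$seed + 100L * i
    note("fitting %s model (seed %d)", mdl, ctl$seed)
    fits[[mdl]] <- if (mdl == "radiation")
      fit_radiation(trips, geo, method = "bayes", control = ctl)
    else fit_gravity(trips, geo, typ, scheme = mdl, kernel = config$kernel,
                     control = ctl)
    note("  DIC %.6g (p_D %.4g)", fits[[mdl]]$dic, fits[[mdl]]$p_d)
  }
  report <- evaluate_models(fits, trips, geo, typ, config$margin)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    if (simulated) {
      write_districts(geo, file.path(config$outdir, "districts.csv"))
      write_trips(trips, file.path(config$outdir, "trips.csv"))
    }
    for (nm in names(fits)) write_fit(fits[[nm]], file.path(config$outdir, "fits"), nm)
    write_evaluation(report, config$outdir)
    writeLines(log, file.path(config$outdir, "log.txt"))
    note("outputs written to %s", config$outdir)
  }
  invisible(list(fits = fits, report = report, geography = geo, trips = trips,
                 typology = typ, dropped = prep$dropped, log = log))
}
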