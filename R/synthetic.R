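# Synthetic origin-destination data with the statistical structure the
# models assume: regionally clustered districts, heterogeneous (log-normal)
# populations with a dominant capital, urbanicity concentrated in the most
# populated districts, and Poisson-distributed trip counts generated from
# known gravity or radiation parameters. Stands in for proprietary
# CDR-derived trip matrices so the whole pipeline is testable.

#' Configuration of the synthetic-geography generator
#'
#' Defaults describe a desk-scale country of 32 districts in 4 regions over
#' a roughly 660 x 880 km bounding box, log-normal district populations with
#' median 1e5 persons, a capital 8x larger than the otherwise-largest
#' district, and a 30% urban district share. Urban labels go to each
#' region's most populated districts (concentrated in high-population
#' districts, but present in every region), so that all eight
#' regional-urbanicity trip categories contain routes with real variation in
#' population and distance while most districts stay rural.
#'
#' @param n_regions Number of administrative level-1 regions.
#' @param districts_per_region Districts per region.
#' @param bbox Bounding box `c(lat_min, lat_max, lon_min, lon_max)` in
#'   decimal degrees.
#' @param jitter_sd Spatial spread of districts around their region centre
#'   (degrees); small relative to the box, so intra-region distances are
#'   stochastically smaller than inter-region ones.
#' @param pop_meanlog,pop_sdlog Log-normal population parameters.
#' @param capital_factor Multiplier applied to the largest district.
#' @param urban_share Fraction of districts labelled urban.
#' @param urban_threshold Threshold used for derived urbanicity labels.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_regions = 4L, districts_per_region = 8L,
                            bbox = c(lat_min = 9, lat_max = 15,
                                     lon_min = -6, lon_max = 2),
                            jitter_sd = 0.35,
                            pop_meanlog = log(1e5), pop_sdlog = 0.9,
                            capital_factor = 8, urban_share = 0.3,
                            urban_threshold = 0.5) {
  if (n_regions * districts_per_region < 2L)
    stop("need at least 2 districts in total", call. = FALSE)
  if (urban_share < 0 || urban_share > 1)
    stop("urban_share must be in [0, 1]", call. = FALSE)
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3])
    stop("bbox must satisfy lat_min < lat_max and lon_min < lon_max", call. = FALSE)
  structure(list(n_regions = as.integer(n_regions),
                 districts_per_region = as.integer(districts_per_region),
                 bbox = bbox, jitter_sd = jitter_sd,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 capital_factor = capital_factor, urban_share = urban_share,
                 urban_threshold = urban_threshold),
            class = "scenario_config")
}

#' Generate a synthetic geography
#'
#' Region centres are placed uniformly in the bounding box (inset by twice
#' the jitter); district centroids are Gaussian-jittered around their region
#' centre, so regions form spatial clusters. Populations are log-normal with
#' the largest district scaled up as the capital; the top `urban_share`
#' districts by population receive urban labels (urban fractions drawn above
#' the threshold, rural fractions below).
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; the same seed reproduces the geography exactly.
#' @return A [geography()].
#' @export
generate_geography <- function(config = scenario_config(), seed = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  nr <- config$n_regions; dpr <- config$districts_per_region
  n <- nr * dpr
  bb <- config$bbox; js <- config$jitter_sd
  inset <- 2 * js
  clat <- stats::runif(nr, bb[1] + inset, bb[2] - inset)
  clon <- stats::runif(nr, bb[3] + inset, bb[4] - inset)
  region <- rep(seq_len(nr), each = dpr)
  lat <- pmin(pmax(clat[region] + stats::rnorm(n, 0, js), bb[1]), bb[2])
  lon <- pmin(pmax(clon[region] + stats::rnorm(n, 0, js), bb[3]), bb[4])
  pop <- stats::rlnorm(n, config$pop_meanlog, config$pop_sdlog)
  pop[which.max(pop)] <- max(pop) * config$capital_factor
  n_urban <- max(1L, round(config$urban_share * n))
  # urban labels go to each region's largest districts: fill by within-region
  # population rank (every region's no. 1 first, then the no. 2s, ...) so the
  # urban set is population-concentrated yet spans regions
  rank_in_region <- stats::ave(-pop, region, FUN = rank)
  urban <- order(rank_in_region, -pop) [seq_len(n_urban)]
  urban <- seq_len(n) %in% urban
  th <- config$urban_threshold
  uf <- numeric(n)
  uf[urban] <- stats::runif(sum(urban), min(th + 0.05, 0.95), 0.95)
  uf[!urban] <- stats::runif(sum(!urban), 0.02, max(th - 0.05, 0.02))
  dd <- data.frame(id = sprintf("d%02d", seq_len(n)),
                   name = sprintf("District %02d", seq_len(n)),
                   region_id = sprintf("r%d", region),
                   population = pop, lat = lat, lon = lon,
                   urban_fraction = uf, stringsAsFactors = FALSE)
  geography(dd, urban_threshold = th)
}

#' Simulate an observed trip matrix
#'
#' Independent Poisson draws at the model's expected counts (the models' own
#' noise assumption); the diagonal stays unmodelled (`NA`).
#'
#' @param geo A [geography()].
#' @param params A [gravity_params()], or a single number in `(0, 1]`
#'   interpreted as the radiation `sigma`.
#' @param seed Integer seed.
#' @param typology Optional [trip_typology()] (gravity only).
#' @return Integer-valued trip matrix with `NA` diagonal.
#' @export
generate_trips <- function(geo, params, seed = 1L, typology = NULL) {
  mu <- if (is.numeric(params) && length(params) == 1L)
    radiation_predict(params, geo)
  else gravity_predict(params, geo, typology)
  idx <- which(!is.na(mu))
  if (any(!is.finite(mu[idx])))
    stop("expected counts are not finite; check the parameters", call. = FALSE)
  set.seed(seed)
  out <- mu
  out[idx] <- stats::rpois(length(idx), mu[idx])
  out
}

#' Calibrate theta to a target median expected count
#'
#' Rescales a gravity parameter set's proportionality constant so the median
#' expected count over all routes equals `target_median`, keeping simulated
#' matrices in a realistic count range for any geography.
#'
#' @param params A [gravity_params()] (its `theta` is replaced).
#' @param geo A [geography()].
#' @param target_median Desired median expected count.
#' @param typology Optional [trip_typology()].
#' @param per_category Calibrate against the *smallest* per-category median
#'   instead of the overall median. For stratified parameter sets whose decay
#'   varies strongly across categories, this guarantees that even the
#'   fastest-decaying trip category keeps counts large enough to identify its
#'   parameters.
#' @return The rescaled [gravity_params()].
#' @export
calibrate_theta <- function(params, geo, target_median = 50, typology = NULL,
                            per_category = FALSE) {
  if (is.null(typology)) typology <- trip_typology(geo)
  mu <- gravity_predict(params, geo, typology)
  keep <- which(!is.na(mu))
  med <- if (per_category) {
    cat_m <- .category_matrix(typology, params$scheme)
    min(tapply(mu[keep], cat_m[keep], stats::median))
  } else stats::median(mu[keep])
  gravity_params(params$theta * target_median / med, params$alpha,
                 params$beta, params$decay, params$kernel, params$scheme)
}

#' Canonical benchmark scenarios
#'
#' Three worlds on one shared geography (so scenarios are directly
#' comparable):
#' \describe{
#'   \item{`basic`}{trips from the basic gravity model (power kernel,
#'     `alpha = 0.9`, `beta = 0.7`, `gamma = 1.5`, `theta` calibrated to a
#'     median expected count of 50).}
#'   \item{`regional_urbanicity`}{trips from the 8-category model with
#'     well-separated decay exponents — intra-regional categories decay
#'     slowly (`gamma` 0.5 to 1.4), inter-regional fast (1.7 to 2.6) — so
#'     travel concentrates within regions. `theta` is calibrated so the
#'     weakest category's median expected count is 20, keeping every
#'     category's parameters identifiable.}
#'   \item{`radiation`}{trips from the finite-system radiation model with
#'     `sigma = 0.2`.}
#' }
#'
#' @param seed Integer seed; the suite regenerates identically under the
#'   same seed.
#' @param config A [scenario_config()].
#' @return Named list of `"synthetic_scenario"` objects, each holding
#'   `geography`, `typology`, `true_params`, `trips`, `model`, `seed`,
#'   `config`.
#' @export
make_benchmark_suite <- function(seed = 1L, config = scenario_config()) {
  geo <- generate_geography(config, seed)
  typ <- trip_typology(geo)
  scen <- function(model, params, trip_seed) {
    structure(list(geography = geo, typology = typ, true_params = params,
                   trips = generate_trips(geo, params, trip_seed, typ),
                   model = model, seed = seed, config = config),
              class = "synthetic_scenario")
  }
  p_basic <- calibrate_theta(
    gravity_params(1, 0.9, 0.7, 1.5, "power", "basic"), geo, 50, typ)
  p_ru <- calibrate_theta(
    gravity_params(1, 0.9, 0.7,
                   c(0.5, 0.8, 1.1, 1.4, 1.7, 2.0, 2.3, 2.6),
                   "power", "regional_urbanicity"),
    geo, 20, typ, per_category = TRUE)
  list(basic = scen("basic", p_basic, seed + 1L),
       regional_urbanicity = scen("regional_urbanicity", p_ru, seed + 2L),
       radiation = scen("radiation", 0.2, seed + 3L))
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic scenario:", x$model, "model, seed", x$seed, "\n")
  print(x$geography)
  tot <- sum(x$trips, na.rm = TRUE)
  cat("  total observed trips:", format(tot, big.mark = ","), "\n")
  invisible(x)
}

#' Write a synthetic scenario to disk
#'
#' `districts.csv` and `trips.csv` in the package's standard formats,
#' `params.yaml` with the generating parameters, and `manifest.json` with
#' the seed and generator configuration.
#'
#' @param scenario A scenario from [make_benchmark_suite()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_districts(scenario$geography, file.path(dir, "districts.csv"))
  write_trips(scenario$trips, file.path(dir, "trips.csv"))
  write_params(scenario$true_params, file.path(dir, "params.yaml"))
  cfg <- unclass(scenario$config)
  cfg$bbox <- as.list(cfg$bbox)
  jsonlite::write_json(list(model = scenario$model, seed = scenario$seed,
                            config = cfg),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
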