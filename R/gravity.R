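# Forward prediction under the eight gravity-model variants:
# four stratification schemes x two distance kernels.
#
#   T_ij = theta * P_i^alpha_c * P_j^beta_c * f(d_ij)
#
# with f(d) = d^(-gamma_c) (power) or exp(-d / D_c) (exponential), where c is
# the trip category of the (i, j) pair under the chosen scheme. theta is a
# single proportionality constant shared across categories (the stratified
# models index alpha, beta and the decay parameter, not theta).

#' Gravity-model parameters
#'
#' @param theta Positive proportionality constant, shared across categories.
#' @param alpha,beta Non-negative exponents on origin and destination
#'   population, one per category of `scheme` (recycled if scalar).
#' @param decay Distance-decay parameter per category: the exponent
#'   `gamma >= 0` for the power kernel, or the deterrence distance `D > 0`
#'   (km) for the exponential kernel.
#' @param kernel `"power"` or `"exponential"`.
#' @param scheme Stratification scheme; see [n_categories()].
#' @return Object of class `"gravity_params"`.
#' @examples
#' gravity_params(0.01, 0.9, 0.7, 1.5, "power", "basic")
#' @export
gravity_params <- function(theta, alpha, beta, decay,
                           kernel = c("power", "exponential"),
                           scheme = c("basic", "urbanicity", "regional",
                                      "regional_urbanicity")) {
  kernel <- match.arg(kernel)
  scheme <- match.arg(scheme)
  C <- n_categories(scheme)
  rec <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, C)
    if (length(x) != C)
      stop(nm, " must have length 1 or ", C, " for scheme '", scheme, "'",
           call. = FALSE)
    if (any(!is.finite(x))) stop(nm, " must be finite", call. = FALSE)
    unname(x)
  }
  if (length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("theta must be a single positive number", call. = FALSE)
  alpha <- rec(alpha, "alpha"); beta <- rec(beta, "beta")
  decay <- rec(decay, "decay")
  if (any(alpha < 0) || any(beta < 0))
    stop("alpha and beta must be non-negative", call. = FALSE)
  if (kernel == "exponential" && any(decay <= 0))
    stop("deterrence distance D must be positive", call. = FALSE)
  if (kernel == "power" && any(decay < 0))
    stop("decay exponent gamma must be non-negative", call. = FALSE)
  structure(list(theta = theta, alpha = alpha, beta = beta, decay = decay,
                 kernel = kernel, scheme = scheme),
            class = "gravity_params")
}

#' @export
print.gravity_params <- function(x, ...) {
  cat("Gravity parameters:", x$scheme, "scheme,", x$kernel, "kernel\n")
  cat("  theta:", format(x$theta, digits = 4), "\n")
  tab <- data.frame(category = category_labels(x$scheme),
                    alpha = x$alpha, beta = x$beta, decay = x$decay)
  names(tab)[4] <- if (x$kernel == "power") "gamma" else "D_km"
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Number of free parameters of a gravity model
#'
#' One shared `theta` plus (`alpha`, `beta`, decay) per category:
#' `1 + 3 * n_categories(scheme)`.
#'
#' @param params A [gravity_params()] (or a fitted model carrying one).
#' @return Integer.
#' @export
count_parameters <- function(params) {
  if (inherits(params, c("gravity_fit", "radiation_fit")))
    return(params$n_params)
  stopifnot(inherits(params, "gravity_params"))
  1L + 3L * n_categories(params$scheme)
}

#' Expected trip counts under a gravity model
#'
#' Evaluates the stratified gravity formula for every ordered
#' origin-destination pair. Within-district travel is never modelled: the
#' diagonal is `NA`.
#'
#' @param params A [gravity_params()].
#' @param geo A [geography()].
#' @param typology Optional [trip_typology()] for `geo`; computed if omitted.
#' @return Numeric matrix of expected counts, `NA` diagonal, id dimnames.
#' @export
gravity_predict <- function(params, geo, typology = NULL) {
  stopifnot(inherits(params, "gravity_params"), inherits(geo, "geography"))
  if (is.null(typology)) typology <- trip_typology(geo)
  if (!identical(typology$ids, geo$districts$id))
    stop("typology does not match the geography", call. = FALSE)
  cat_m <- .category_matrix(typology, params$scheme)
  d <- geo$distance
  off <- row(d) != col(d)
  if (params$kernel == "power" && any(d[off] == 0))
    stop("power kernel is singular at zero distance between distinct districts",
         call. = FALSE)
  P <- geo$districts$population
  n <- length(P)
  ci <- cat_m
  lmu <- matrix(NA_real_, n, n, dimnames = dimnames(d))
  idx <- which(off)
  c_ <- ci[idx]
  lmu[idx] <- log(params$theta) +
    params$alpha[c_] * log(P[row(d)[idx]]) +
    params$beta[c_] * log(P[col(d)[idx]]) +
    if (params$kernel == "power") -params$decay[c_] * log(d[idx])
    else -d[idx] / params$decay[c_]
  exp(lmu)
}

#' Read / write gravity parameters as YAML
#'
#' The file carries scalars `theta`, `kernel`, `scheme`, `model: gravity` and
#' a `categories` table with `category, alpha, beta, decay` rows. Radiation
#' parameters are written as `model: radiation` with scalar `sigma`.
#'
#' @param path File path.
#' @return `read_params()` returns a [gravity_params()] or, for
#'   `model: radiation`, a list with element `sigma`.
#' @export
read_params <- function(path) {
  y <- yaml::read_yaml(path)
  if (identical(y$model, "radiation"))
    return(list(model = "radiation", sigma = as.numeric(y$sigma)))
  cats <- y$categories
  gravity_params(theta = as.numeric(y$theta),
                 alpha = vapply(cats, function(r) as.numeric(r$alpha), 0),
                 beta = vapply(cats, function(r) as.numeric(r$beta), 0),
                 decay = vapply(cats, function(r) as.numeric(r$decay), 0),
                 kernel = y$kernel, scheme = y$scheme)
}

#' @rdname read_params
#' @param params A [gravity_params()], or a number interpreted as the
#'   radiation `sigma`.
#' @export
write_params <- function(params, path) {
  if (is.numeric(params)) {
    yaml::write_yaml(list(model = "radiation", sigma = unname(params)), path,
                     precision = 15)
    return(invisible(path))
  }
  stopifnot(inherits(params, "gravity_params"))
  labs <- category_labels(params$scheme)
  cats <- lapply(seq_along(labs), function(i)
    list(category = labs[i], alpha = params$alpha[i], beta = params$beta[i],
         decay = params$decay[i]))
  yaml::write_yaml(list(model = "gravity", scheme = params$scheme,
                        kernel = params$kernel, theta = params$theta,
                        categories = cats), path, precision = 15)
  invisible(path)
}
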