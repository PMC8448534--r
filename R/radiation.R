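# Finite-system radiation model. The flux from origin i to destination j
# depends on the population s_ij intervening between them:
#
#   T_ij = sigma * P_i * (1 - P_i/P)^(-1) * P_i P_j /
#          [ (P_i + s_ij) (P_i + P_j + s_ij) ]
#
# sigma is the proportion of the total population P travelling per unit
# period, so T_i = sigma * P_i trips emanate from origin i. s_ij is computed
# from centroids: the summed population of districts strictly closer to i
# than j is (cumulative definition; distance ties broken by district order).
# Under that definition the finite-system normalisation is exact: each
# predicted row sums to sigma * P_i identically.

#' Intervening population matrix
#'
#' For each origin, destinations are ranked by centroid distance and
#' `s[i, j]` is the total population of districts strictly closer to `i`
#' than `j` is (excluding both endpoints). The nearest destination of every
#' origin has `s = 0`. Ties in distance are broken by district order,
#' deterministically.
#'
#' @param geo A [geography()].
#' @return Numeric matrix (persons), `NA` diagonal, id dimnames.
#' @export
intervening_population <- function(geo) {
  stopifnot(inherits(geo, "geography"))
  P <- geo$districts$population
  n <- length(P)
  if (n < 2L) stop("at least 2 districts are required", call. = FALSE)
  s <- matrix(NA_real_, n, n, dimnames = dimnames(geo$distance))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(geo$distance[i, others], others)]
    s[i, ord] <- cumsum(c(0, P[ord[-length(ord)]]))
  }
  s
}

#' Expected trip counts under the radiation model
#'
#' @param sigma Proportion of the total population travelling per unit
#'   period, normally in `(0, 1]`; values above 1 are allowed (average trips
#'   per person can exceed one per period when fitted to high-volume trip
#'   data). A value of 1 gives the "unit" prediction used by the closed-form
#'   fit.
#' @param geo A [geography()].
#' @param s Optional precomputed [intervening_population()] matrix.
#' @return Numeric matrix of expected counts, `NA` diagonal. Every row `i`
#'   sums to `sigma * P_i` exactly.
#' @export
radiation_predict <- function(sigma, geo, s = NULL) {
  stopifnot(inherits(geo, "geography"))
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a single positive value", call. = FALSE)
  if (is.null(s)) s <- intervening_population(geo)
  P <- geo$districts$population
  Ptot <- geo$total_population
  if (any(P >= Ptot))
    stop("radiation normalization is degenerate when one district holds the entire population",
         call. = FALSE)
  Pi <- matrix(P, nrow = length(P), ncol = length(P))
  Pj <- t(Pi)
  T_ <- sigma * Pi / (1 - Pi / Ptot) * Pi * Pj / ((Pi + s) * (Pi + Pj + s))
  dimnames(T_) <- dimnames(geo$distance)
  diag(T_) <- NA_real_
  T_
}

#' Fit the radiation model's travelling proportion
#'
#' Fits `sigma` to an observed trip matrix under a Poisson likelihood.
#' Because the prediction is linear in `sigma`, the maximum-likelihood
#' estimate is closed-form: `sigma_hat = sum(m_ij) / sum(u_ij)` where `u` is
#' the unit-`sigma` prediction over the observed routes. With
#' `method = "bayes"` a Gamma prior is used, the posterior is the conjugate
#' Gamma distribution, and the deviance trace and DIC are computed so the
#' radiation model can be ranked on the same DIC scale as the gravity fits.
#'
#' @param obs Observed trip matrix (non-negative; non-integers are rounded).
#' @param geo A [geography()].
#' @param method `"mle"` (closed form) or `"bayes"` (conjugate posterior
#'   sampling plus DIC).
#' @param control An [mcmc_control()]; for `"bayes"` its `chains`, `samples`,
#'   `seed`, `prior_shape` and `prior_rate` are used.
#' @return Object of class `"radiation_fit"`: `sigma` (posterior mean or
#'   MLE), `sigma_mle`, `samples`/`deviance` (bayes only), `dic`, `p_d`,
#'   `mean_deviance`, `n_params` (= 1), `n_pairs`, `log_lik`.
#' @export
fit_radiation <- function(obs, geo, method = c("bayes", "mle"),
                          control = mcmc_control()) {
  method <- match.arg(method)
  stopifnot(inherits(geo, "geography"))
  obs <- .validate_trips(obs, geo$districts$id)
  obs <- .round_counts(obs)
  keep <- which(row(obs) != col(obs) & !is.na(obs))
  m <- obs[keep]
  if (sum(m) == 0)
    stop("all observed counts are zero: sigma is undefined at the boundary",
         call. = FALSE)
  u <- radiation_predict(1, geo)[keep]
  sig_mle <- sum(m) / sum(u)
  sumlf <- sum(lfactorial(m))
  ll <- function(sig) sum(m * (log(sig) + log(u))) - sig * sum(u) - sumlf
  out <- list(sigma_mle = sig_mle, n_params = 1L, n_pairs = length(m),
              obs_total = sum(m), method = method, model = "radiation")
  if (method == "mle") {
    out$sigma <- sig_mle
    out$log_lik <- ll(sig_mle)
    out$mean_deviance <- out$dic <- -2 * out$log_lik
    out$p_d <- 0
  } else {
    shape <- control$prior_shape + sum(m)
    rate <- control$prior_rate + sum(u)
    draws <- vector("list", control$chains)
    for (ch in seq_len(control$chains)) {
      set.seed(control$seed + ch - 1L)
      draws[[ch]] <- stats::rgamma(control$samples, shape = shape, rate = rate)
    }
    dev <- lapply(draws, function(s) vapply(s, function(x) -2 * ll(x), 0))
    sig_hat <- mean(unlist(draws))
    d <- compute_dic(unlist(dev), -2 * ll(sig_hat))
    out$sigma <- sig_hat
    out$samples <- lapply(draws, function(x) matrix(x, ncol = 1, dimnames = list(NULL, "sigma")))
    out$deviance <- dev
    out$posterior <- list(shape = shape, rate = rate)
    out$log_lik <- ll(sig_hat)
    out$mean_deviance <- d$mean_deviance
    out$p_d <- d$p_d
    out$dic <- d$dic
    out$rhat <- c(sigma = if (control$chains > 1) .rhat(lapply(out$samples, function(x) x[, 1])) else NA_real_)
  }
  out$geo <- geo
  structure(out, class = "radiation_fit")
}

#' @export
print.radiation_fit <- function(x, ...) {
  cat("Radiation model fit (", x$method, "), ", x$n_pairs, " routes\n", sep = "")
  cat("  sigma:", format(x$sigma, digits = 6),
      " (MLE:", format(x$sigma_mle, digits = 6), ")\n")
  cat("  DIC:", format(x$dic, digits = 8), " p_D:", format(x$p_d, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.radiation_fit <- function(object, ...) c(sigma = object$sigma)

#' @export
predict.radiation_fit <- function(object, geo = object$geo, ...) {
  radiation_predict(object$sigma, geo)
}

#' @export
simulate.radiation_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  idx <- which(!is.na(mu))
  replicate(nsim, {
    out <- mu
    out[idx] <- stats::rpois(length(idx), mu[idx])
    out
  }, simplify = FALSE)
}

# round observed averages to Poisson support, reporting when rounding occurs
.round_counts <- function(obs) {
  off <- which(row(obs) != col(obs) & !is.na(obs))
  nonint <- sum(obs[off] != round(obs[off]))
  if (nonint > 0) {
    message("rounded ", nonint, " non-integer observed counts to the nearest integer")
    obs[off] <- round(obs[off])
  }
  obs
}
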