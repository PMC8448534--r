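# Bayesian fitting of gravity models under the Poisson likelihood
# m_ij ~ Pois(T_ij), with independent Gamma(prior_shape, prior_rate) priors
# on theta and on every per-category alpha, beta and decay parameter.
#
# Sampler: all parameters are positive, so the chain moves on the log scale.
# A Laplace approximation (posterior mode via BFGS with analytic gradient,
# covariance from the inverse Hessian) seeds a full-block Gaussian
# random-walk Metropolis whose scalar step size adapts towards a 23.4%
# acceptance rate during burn-in; halfway through burn-in the proposal
# covariance is re-estimated from the burn-in draws (useful when the
# curvature at the mode understates posterior correlations). Both are frozen
# after burn-in, keeping the retained chain a valid Metropolis sample. The
# fit is reproducible given the seed; chains c = 1..C use seed + c - 1.

#' MCMC configuration
#'
#' @param chains Number of chains (>= 2 recommended for convergence
#'   diagnostics).
#' @param burn_in Burn-in iterations per chain (adaptation happens here).
#' @param samples Retained draws per chain (after thinning).
#' @param thin Thinning interval.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param prior_shape,prior_rate Gamma prior hyperparameters applied to every
#'   parameter; the 0.001/0.001 default is the conventional uninformative
#'   choice.
#' @param rhat_threshold Warn when any parameter's split-Rhat exceeds this.
#' @param adapt_target Target acceptance rate during burn-in.
#' @return A list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(chains = 2L, burn_in = 2000L, samples = 5000L,
                         thin = 5L, seed = 1234L,
                         prior_shape = 0.001, prior_rate = 0.001,
                         rhat_threshold = 1.1, adapt_target = 0.234) {
  stopifnot(chains >= 1, burn_in >= 0, samples >= 1, thin >= 1,
            prior_shape > 0, prior_rate > 0)
  structure(list(chains = as.integer(chains), burn_in = as.integer(burn_in),
                 samples = as.integer(samples), thin = as.integer(thin),
                 seed = as.integer(seed), prior_shape = prior_shape,
                 prior_rate = prior_rate, rhat_threshold = rhat_threshold,
                 adapt_target = adapt_target),
            class = "mcmc_control")
}

#' Read an MCMC configuration from YAML
#'
#' Recognised keys: `chains, burn_in, samples, thin, seed, prior_shape,
#' prior_rate, rhat_threshold`.
#'
#' @param path YAML file path.
#' @return An [mcmc_control()].
#' @export
read_mcmc_control <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(mcmc_control, y[intersect(names(y), names(formals(mcmc_control)))])
}

# ---- internal machinery ------------------------------------------------------

# flatten matrices to the observed off-diagonal routes used by the likelihood
.pair_data <- function(obs, geo, typology, scheme) {
  cat_m <- .category_matrix(typology, scheme)
  keep <- which(row(obs) != col(obs) & !is.na(obs))
  m <- obs[keep]
  if (length(m) == 0L) stop("no observed routes to fit", call. = FALSE)
  C <- n_categories(scheme)
  cat <- cat_m[keep]
  present <- sort(unique(cat))
  if (!identical(present, seq_len(C))) {
    missing <- setdiff(seq_len(C), present)
    stop("no observed routes in categor", if (length(missing) > 1) "ies " else "y ",
         paste(category_labels(scheme)[missing], collapse = ", "),
         "; this scheme cannot be fitted to these data", call. = FALSE)
  }
  P <- geo$districts$population
  i <- row(obs)[keep]; j <- col(obs)[keep]
  d <- geo$distance[keep]
  if (any(d <= 0))
    stop("zero centroid distance between distinct districts; cannot fit a distance kernel",
         call. = FALSE)
  list(m = m, lPi = log(P[i]), lPj = log(P[j]), d = d, ld = log(d),
       cat = cat, C = C, n = length(m), sumlf = sum(lfactorial(m)),
       keep = keep)
}

# returns c(log posterior, log likelihood sans lfactorial term)
.make_logpost <- function(pd, kernel, a0, b0) {
  C <- pd$C
  ia <- 2:(1 + C); ib <- (2 + C):(1 + 2 * C); ig <- (2 + 2 * C):(1 + 3 * C)
  m <- pd$m; lPi <- pd$lPi; lPj <- pd$lPj; ld <- pd$ld; d <- pd$d; ct <- pd$cat
  power <- kernel == "power"
  function(eta) {
    al <- exp(eta[ia]); be <- exp(eta[ib]); de <- exp(eta[ig])
    lmu <- eta[1] + al[ct] * lPi + be[ct] * lPj +
      if (power) -de[ct] * ld else -d / de[ct]
    ll <- sum(m * lmu) - sum(exp(lmu))
    c(ll + sum(a0 * eta - b0 * exp(eta)), ll)
  }
}

.make_grad <- function(pd, kernel, a0, b0) {
  C <- pd$C
  ia <- 2:(1 + C); ib <- (2 + C):(1 + 2 * C); ig <- (2 + 2 * C):(1 + 3 * C)
  m <- pd$m; lPi <- pd$lPi; lPj <- pd$lPj; ld <- pd$ld; d <- pd$d
  ct <- factor(pd$cat, levels = seq_len(C))
  power <- kernel == "power"
  function(eta) {
    al <- exp(eta[ia]); be <- exp(eta[ib]); de <- exp(eta[ig])
    cti <- as.integer(ct)
    lmu <- eta[1] + al[cti] * lPi + be[cti] * lPj +
      if (power) -de[cti] * ld else -d / de[cti]
    r <- m - exp(lmu)
    gth <- sum(r)
    ga <- al * as.vector(rowsum(r * lPi, ct))
    gb <- be * as.vector(rowsum(r * lPj, ct))
    gd <- if (power) -de * as.vector(rowsum(r * ld, ct))
          else as.vector(rowsum(r * d, ct)) / de
    c(gth, ga, gb, gd) + (a0 - b0 * exp(eta))
  }
}

# Laplace approximation: posterior mode and inverse-Hessian covariance
.fit_map <- function(pd, kernel, a0, b0) {
  C <- pd$C; p <- 1L + 3L * C
  f <- .make_logpost(pd, kernel, a0, b0)
  g <- .make_grad(pd, kernel, a0, b0)
  de0 <- if (kernel == "power") rep(1, C) else rep(mean(pd$d), C)
  eta0 <- c(0, rep(0, 2 * C), log(de0))
  lmu0 <- pd$lPi + pd$lPj +
    (if (kernel == "power") -pd$ld else -pd$d / de0[pd$cat])
  eta0[1] <- log(max(sum(pd$m), 1) / sum(exp(lmu0)))
  opt <- stats::optim(eta0, fn = function(e) -f(e)[1], gr = function(e) -g(e),
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12),
                      hessian = TRUE)
  S <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  R <- if (!is.null(S)) tryCatch(chol((S + t(S)) / 2), error = function(e) NULL) else NULL
  if (is.null(R)) {
    dH <- pmax(abs(diag(opt$hessian)), 1e-8)
    R <- diag(sqrt(1 / dH), p)
  }
  list(par = opt$par, chol_cov = R, logpost = f, value = -opt$value,
       convergence = opt$convergence)
}

.param_names <- function(scheme, kernel) {
  C <- n_categories(scheme)
  lab <- .short_labels(scheme)
  dn <- if (kernel == "power") "gamma" else "D"
  if (scheme == "basic") c("theta", "alpha", "beta", dn)
  else c("theta", paste0("alpha.", lab), paste0("beta.", lab), paste0(dn, ".", lab))
}

.short_labels <- function(scheme) {
  switch(scheme,
         basic = "all",
         urbanicity = c("rr", "ru", "ur", "uu"),
         regional = c("intra", "inter"),
         regional_urbanicity = c(paste0("intra.", c("rr", "ru", "ur", "uu")),
                                 paste0("inter.", c("rr", "ru", "ur", "uu"))))
}

#' Fit a gravity model by MCMC
#'
#' Samples the posterior of the gravity parameters (`theta` plus per-category
#' `alpha`, `beta` and decay) given an observed trip matrix, under the
#' Poisson likelihood and independent Gamma priors, and computes the Deviance
#' Information Criterion.
#'
#' Non-integer observed counts (e.g. monthly averages) are rounded to the
#' nearest integer before fitting, with a message. Routes recorded as `NA`
#' are structurally missing and excluded; observed zeros are retained.
#'
#' @param obs Observed trip matrix aligned with `geo` (id dimnames).
#' @param geo A [geography()].
#' @param typology Optional [trip_typology()]; computed from `geo` if omitted.
#' @param scheme Stratification scheme (see [n_categories()]).
#' @param kernel `"power"` or `"exponential"`.
#' @param control An [mcmc_control()].
#' @return Object of class `"gravity_fit"` with elements `params`
#'   (posterior-mean [gravity_params()]), `samples` (list of per-chain
#'   matrices on the natural scale), `deviance` (per-chain traces), `dic`,
#'   `p_d`, `mean_deviance`, `rhat`, `ess`, `accept_rate`, `map` (posterior
#'   mode), `n_params`, `n_pairs`, `obs_total`, `control`, and the inputs
#'   needed by `predict()`/`residuals()`.
#' @seealso [compute_dic()], [fit_radiation()], [rank_models()]
#' @examples
#' \donttest{
#' sc <- make_benchmark_suite(seed = 7)$basic
#' fit <- fit_gravity(sc$trips, sc$geography, scheme = "basic",
#'                    control = mcmc_control(burn_in = 200, samples = 200, thin = 1))
#' summary(fit)
#' }
#' @export
fit_gravity <- function(obs, geo, typology = NULL,
                        scheme = c("basic", "urbanicity", "regional",
                                   "regional_urbanicity"),
                        kernel = c("power", "exponential"),
                        control = mcmc_control()) {
  scheme <- match.arg(scheme)
  kernel <- match.arg(kernel)
  stopifnot(inherits(geo, "geography"), inherits(control, "mcmc_control"))
  if (is.null(typology)) typology <- trip_typology(geo)
  if (!identical(typology$ids, geo$districts$id))
    stop("typology does not match the geography", call. = FALSE)
  obs <- .validate_trips(obs, geo$districts$id)
  obs <- .round_counts(obs)
  pd <- .pair_data(obs, geo, typology, scheme)
  a0 <- control$prior_shape; b0 <- control$prior_rate
  map <- .fit_map(pd, kernel, a0, b0)
  logpost <- map$logpost
  p <- length(map$par)
  pn <- .param_names(scheme, kernel)

  n_iter <- control$burn_in + control$samples * control$thin
  scale0 <- 2.38 / sqrt(p)
  samples <- vector("list", control$chains)
  devs <- vector("list", control$chains)
  acc_rates <- numeric(control$chains)
  for (ch in seq_len(control$chains)) {
    set.seed(control$seed + ch - 1L)
    eta <- map$par + 0.1 * scale0 * drop(stats::rnorm(p) %*% map$chol_cov)
    cur <- logpost(eta)
    if (!is.finite(cur[1])) { eta <- map$par; cur <- logpost(eta) }
    ls <- log(scale0)
    R <- map$chol_cov
    out <- matrix(NA_real_, control$samples, p, dimnames = list(NULL, pn))
    dv <- numeric(control$samples)
    buf <- if (control$burn_in >= 200L)
      matrix(NA_real_, control$burn_in %/% 2L, p) else NULL
    n_acc <- 0L
    for (t in seq_len(n_iter)) {
      prop <- eta + exp(ls) * drop(stats::rnorm(p) %*% R)
      cand <- logpost(prop)
      acc <- is.finite(cand[1]) && log(stats::runif(1)) < cand[1] - cur[1]
      if (acc) { eta <- prop; cur <- cand }
      if (t <= control$burn_in) {
        ls <- ls + (as.numeric(acc) - control$adapt_target) * min(0.05, 1 / sqrt(t))
        if (!is.null(buf)) {
          half <- nrow(buf)
          if (t <= half) buf[t, ] <- eta
          if (t == half) {
            # re-estimate the proposal shape from the first half of burn-in
            S2 <- stats::cov(buf) + diag(1e-12, p)
            R2 <- tryCatch(chol(S2), error = function(e) NULL)
            if (!is.null(R2) && all(is.finite(R2))) {
              R <- R2
              ls <- log(scale0)
            }
          }
        }
      } else {
        n_acc <- n_acc + acc
        rel <- t - control$burn_in
        if (rel %% control$thin == 0L) {
          k <- rel %/% control$thin
          out[k, ] <- exp(eta)
          dv[k] <- -2 * (cur[2] - pd$sumlf)
        }
      }
    }
    samples[[ch]] <- out
    devs[[ch]] <- dv
    acc_rates[ch] <- n_acc / (n_iter - control$burn_in)
  }

  all_s <- do.call(rbind, samples)
  post_mean <- colMeans(all_s)
  C <- pd$C
  params_hat <- gravity_params(post_mean[1],
                               post_mean[2:(1 + C)],
                               post_mean[(2 + C):(1 + 2 * C)],
                               post_mean[(2 + 2 * C):(1 + 3 * C)],
                               kernel, scheme)
  dev_at_mean <- -2 * (logpost(log(post_mean))[2] - pd$sumlf)
  dic <- compute_dic(unlist(devs), dev_at_mean)
  rhat <- if (control$chains > 1)
    vapply(seq_len(p), function(k) .rhat(lapply(samples, function(s) s[, k])), 0)
  else rep(NA_real_, p)
  ess <- vapply(seq_len(p), function(k)
    sum(vapply(samples, function(s) .ess(s[, k]), 0)), 0)
  names(rhat) <- names(ess) <- pn
  fit <- structure(
    list(params = params_hat, samples = samples, deviance = devs,
         dic = dic$dic, p_d = dic$p_d, mean_deviance = dic$mean_deviance,
         deviance_at_mean = dev_at_mean,
         rhat = rhat, ess = ess, accept_rate = acc_rates,
         map = stats::setNames(exp(map$par), pn),
         scheme = scheme, kernel = kernel, model = scheme,
         n_params = 1L + 3L * C, n_pairs = pd$n, obs_total = sum(pd$m),
         control = control, geo = geo, typology = typology, obs = obs),
    class = "gravity_fit")
  if (control$chains > 1 && any(rhat > control$rhat_threshold, na.rm = TRUE))
    warning("convergence warning: split-Rhat > ", control$rhat_threshold,
            " for ", paste(pn[rhat > control$rhat_threshold], collapse = ", "))
  fit
}

#' Deviance Information Criterion from a deviance trace
#'
#' Spiegelhalter's form: `p_D = mean(deviance) - D(posterior means)` and
#' `DIC = mean(deviance) + p_D`.
#'
#' @param deviance_trace Deviance (`-2 log L`) recorded at each retained
#'   posterior draw.
#' @param deviance_at_means Deviance evaluated at the posterior means of the
#'   parameters.
#' @return List with `mean_deviance`, `p_d`, `dic`.
#' @examples
#' compute_dic(c(2, 4), 2)  # mean 3, p_D 1, DIC 4
#' @export
compute_dic <- function(deviance_trace, deviance_at_means) {
  if (length(deviance_trace) == 0L || any(!is.finite(deviance_trace)))
    stop("deviance trace must be non-empty and finite", call. = FALSE)
  if (length(deviance_at_means) != 1L || !is.finite(deviance_at_means))
    stop("deviance at posterior means must be a single finite value", call. = FALSE)
  dbar <- mean(deviance_trace)
  p_d <- dbar - deviance_at_means
  list(mean_deviance = dbar, p_d = p_d, dic = dbar + p_d)
}

# split-Rhat (Gelman-Rubin on half-chains)
.rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  if (W == 0) return(1)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size by the initial-positive-pair-sum rule
.ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 250L), plot = FALSE)$acf[-1]
  s <- 0; k <- 1L
  while (k + 1L <= length(ac)) {
    g <- ac[k] + ac[k + 1L]
    if (!is.finite(g) || g <= 0) break
    s <- s + g
    k <- k + 2L
  }
  min(n, n / (1 + 2 * s))
}

# ---- methods -----------------------------------------------------------------

#' @export
print.gravity_fit <- function(x, ...) {
  cat("Gravity model fit:", x$scheme, "scheme,", x$kernel, "kernel\n")
  cat("  ", x$n_pairs, " routes, ", x$n_params, " parameters, ",
      x$control$chains, " chains x ", x$control$samples, " draws\n", sep = "")
  cat("  DIC:", format(x$dic, digits = 8), " p_D:", format(x$p_d, digits = 4), "\n")
  if (!all(is.na(x$rhat)))
    cat("  max split-Rhat:", format(max(x$rhat, na.rm = TRUE), digits = 4), "\n")
  cat("  posterior mean parameters:\n")
  print(x$params)
  invisible(x)
}

#' @export
summary.gravity_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  all_s <- do.call(rbind, object$samples)
  tab <- cbind(mean = colMeans(all_s),
               sd = apply(all_s, 2, stats::sd),
               t(apply(all_s, 2, stats::quantile, probs = probs)),
               rhat = object$rhat, ess = object$ess)
  structure(list(table = tab, dic = object$dic, p_d = object$p_d,
                 scheme = object$scheme, kernel = object$kernel,
                 accept_rate = object$accept_rate),
            class = "summary.gravity_fit")
}

#' @export
print.summary.gravity_fit <- function(x, ...) {
  cat("Posterior summary (", x$scheme, " scheme, ", x$kernel, " kernel)\n", sep = "")
  print(round(x$table, 4))
  cat("DIC:", format(x$dic, digits = 8), " p_D:", format(x$p_d, digits = 4),
      " acceptance:", paste(round(x$accept_rate, 3), collapse = "/"), "\n")
  invisible(x)
}

#' @export
coef.gravity_fit <- function(object, ...) {
  all_s <- do.call(rbind, object$samples)
  colMeans(all_s)
}

#' @export
predict.gravity_fit <- function(object, geo = object$geo,
                                typology = NULL, ...) {
  if (is.null(typology))
    typology <- if (identical(geo, object$geo)) object$typology else trip_typology(geo)
  gravity_predict(object$params, geo, typology)
}

#' @export
simulate.gravity_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  idx <- which(!is.na(mu))
  replicate(nsim, {
    out <- mu
    out[idx] <- stats::rpois(length(idx), mu[idx])
    out
  }, simplify = FALSE)
}

#' @export
residuals.gravity_fit <- function(object,
                                  type = c("pearson", "deviance", "response"),
                                  ...) {
  type <- match.arg(type)
  mu <- predict(object)
  m <- object$obs
  r <- switch(type,
    response = m - mu,
    pearson = (m - mu) / sqrt(mu),
    deviance = {
      dd <- 2 * (ifelse(m > 0, m * log(m / mu), 0) - (m - mu))
      sign(m - mu) * sqrt(pmax(dd, 0))
    })
  r
}

#' @export
deviance.gravity_fit <- function(object, ...) object$deviance_at_mean

#' @export
logLik.gravity_fit <- function(object, ...) {
  structure(-object$deviance_at_mean / 2, df = object$n_params,
            nobs = object$n_pairs, class = "logLik")
}

#' @export
plot.gravity_fit <- function(x, which = NULL, ...) {
  pn <- colnames(x$samples[[1]])
  if (is.null(which)) which <- pn[seq_len(min(4L, length(pn)))]
  which <- intersect(which, pn)
  old <- graphics::par(mfrow = c(length(which), 2),
                       mar = c(3.5, 3.5, 2, 0.5), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(old))
  for (p in which) {
    rng <- range(unlist(lapply(x$samples, function(s) s[, p])))
    graphics::plot(x$samples[[1]][, p], type = "l", col = 1, ylim = rng,
                   xlab = "iteration", ylab = p, main = paste("trace:", p))
    if (length(x$samples) > 1)
      for (ch in 2:length(x$samples))
        graphics::lines(x$samples[[ch]][, p], col = ch)
    graphics::hist(unlist(lapply(x$samples, function(s) s[, p])), breaks = 40,
                   main = paste("posterior:", p), xlab = p)
  }
  invisible(x)
}

#' Serialize a fit to disk
#'
#' Writes per-chain CSV files of the retained draws (with a `deviance`
#' column) and a JSON metadata file (scheme, kernel, DIC, p_D, Rhat, ESS,
#' acceptance rates, control settings).
#'
#' @param fit A `gravity_fit` or `radiation_fit`.
#' @param dir Output directory (created if needed).
#' @param name File stem; defaults to the model name.
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir, name = NULL) {
  if (is.null(name))
    name <- if (inherits(fit, "radiation_fit")) "radiation" else fit$scheme
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(fit$samples)) {
    for (ch in seq_along(fit$samples)) {
      p <- file.path(dir, sprintf("%s_chain%d.csv", name, ch))
      df <- as.data.frame(fit$samples[[ch]])
      df$deviance <- fit$deviance[[ch]]
      utils::write.csv(df, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  meta <- list(model = if (inherits(fit, "radiation_fit")) "radiation" else fit$scheme,
               kernel = fit$kernel, n_params = fit$n_params,
               n_pairs = fit$n_pairs, obs_total = fit$obs_total,
               dic = fit$dic, p_d = fit$p_d, mean_deviance = fit$mean_deviance,
               rhat = as.list(fit$rhat), ess = as.list(fit$ess),
               accept_rate = fit$accept_rate,
               control = unclass(fit$control))
  mp <- file.path(dir, paste0(name, "_meta.json"))
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mp))
}
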