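# Small deterministic fixtures shared across the suite.

test_districts <- function() {
  data.frame(
    id = c("a", "b", "c", "d", "e"),
    name = paste("District", 1:5),
    region_id = c("r1", "r1", "r1", "r2", "r2"),
    population = c(250000, 90000, 40000, 800000, 60000),
    lat = c(10.0, 10.3, 10.8, 12.5, 12.9),
    lon = c(-1.0, -0.5, -1.4, 0.8, 0.2),
    urban_fraction = c(0.8, 0.3, 0.1, 0.9, 0.45),
    stringsAsFactors = FALSE
  )
}

test_geography <- function() geography(test_districts())

# six districts covering all eight regional-urbanicity categories
test_districts8 <- function() {
  data.frame(
    id = sprintf("d%d", 1:6),
    name = sprintf("District %d", 1:6),
    region_id = c("r1", "r1", "r1", "r2", "r2", "r2"),
    population = c(500000, 300000, 50000, 400000, 70000, 30000),
    lat = c(10.1, 10.4, 10.7, 13.0, 13.3, 13.6),
    lon = c(-1.2, -0.8, -1.5, 0.5, 0.9, 0.1),
    urban_fraction = c(0.9, 0.7, 0.2, 0.85, 0.3, 0.1),
    stringsAsFactors = FALSE
  )
}

# short chains for fast distributional smoke tests
quick_control <- function(seed = 42L, ...) {
  mcmc_control(chains = 2L, burn_in = 500L, samples = 400L, thin = 1L,
               seed = seed, ...)
}

# brute-force gravity evaluation: naive double loop over the formula
brute_gravity <- function(params, geo, typology) {
  dd <- geo$districts
  n <- nrow(dd)
  cat_m <- switch(params$scheme,
                  basic = matrix(1L, n, n),
                  urbanicity = typology$k,
                  regional = typology$m,
                  regional_urbanicity = typology$n)
  out <- matrix(NA_real_, n, n, dimnames = list(dd$id, dd$id))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    c_ <- cat_m[i, j]
    f <- if (params$kernel == "power") geo$distance[i, j]^(-params$decay[c_])
         else exp(-geo$distance[i, j] / params$decay[c_])
    out[i, j] <- params$theta * dd$population[i]^params$alpha[c_] *
      dd$population[j]^params$beta[c_] * f
  }
  out
}

# brute-force finite-system radiation evaluation per pair
brute_radiation <- function(sigma, geo) {
  dd <- geo$districts
  P <- dd$population
  Ptot <- sum(P)
  n <- nrow(dd)
  out <- matrix(NA_real_, n, n, dimnames = list(dd$id, dd$id))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    # population strictly closer to i than j (ties by district order)
    s <- 0
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      dk <- geo$distance[i, k]; dj <- geo$distance[i, j]
      if (dk < dj || (dk == dj && k < j)) s <- s + P[k]
    }
    out[i, j] <- sigma * P[i] / (1 - P[i] / Ptot) * P[i] * P[j] /
      ((P[i] + s) * (P[i] + P[j] + s))
  }
  out
}

random_geography <- function(seed, n = 6L) {
  set.seed(seed)
  dd <- data.frame(
    id = sprintf("g%02d", seq_len(n)),
    name = sprintf("G %d", seq_len(n)),
    region_id = sample(c("r1", "r2"), n, replace = TRUE),
    population = exp(stats::runif(n, log(2e4), log(8e5))),
    lat = stats::runif(n, 5, 15),
    lon = stats::runif(n, -5, 5),
    urban_fraction = stats::runif(n),
    stringsAsFactors = FALSE
  )
  geography(dd)
}
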