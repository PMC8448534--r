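test_that("OD proportions are row-normalized shares", {
  ids <- letters[1:4]
  m <- matrix(5, 4, 4, dimnames = list(ids, ids)); diag(m) <- NA
  p <- od_proportions(m)
  expect_equal(p[!is.na(p)], rep(1 / 3, 12))
  m2 <- matrix(c(NA, 2, 6,
                 1, NA, 1,
                 1, 1, NA), 3, 3, byrow = TRUE)
  expect_equal(unname(od_proportions(m2)[1, 2:3]), c(0.25, 0.75))
  set.seed(15)
  r <- matrix(runif(36, 0, 10), 6, 6); diag(r) <- NA
  pr <- od_proportions(r)
  expect_equal(unname(rowSums(pr, na.rm = TRUE)), rep(1, 6), tolerance = 1e-12)
  for (i in 1:6) for (j in 1:6)
    if (i != j) expect_equal(pr[i, j], r[i, j] / sum(r[i, ], na.rm = TRUE))
  # zero rows are flagged, not silently normalized
  r[2, ] <- 0; diag(r) <- NA
  expect_message(pz <- od_proportions(r), "no trips")
  expect_true(all(is.na(pz[2, ])))
  expect_equal(attr(pz, "zero_rows"), c(2L))
  r[3, 1] <- -1
  expect_error(od_proportions(r), "non-negative")
})

test_that("percent change in DIC uses the improvement-positive convention", {
  expect_equal(percent_change_dic(100, 100), 0)
  expect_equal(percent_change_dic(59, 100), 41)
  expect_equal(percent_change_dic(180, 100), -80)
  expect_error(percent_change_dic(1, 0), "non-zero")
})

test_that("ratio accuracy counts routes within the margin per trip type", {
  geo <- geography(test_districts8())
  typ <- trip_typology(geo)
  set.seed(16)
  obs <- matrix(rpois(36, 50), 6, 6,
                dimnames = list(geo$districts$id, geo$districts$id))
  diag(obs) <- NA
  # perfect prediction: every ratio 1, accuracy 1 in every category
  perfect <- ratio_accuracy(obs, obs, typ)
  expect_true(all(perfect$accuracy[perfect$n > 0] == 1))
  expect_true(all(perfect$median_ratio[perfect$n > 0] == 1))
  # uniform 20% overestimate: accuracy 0 at the 10% margin
  over <- ratio_accuracy(1.2 * obs, obs, typ)
  expect_true(all(over$accuracy[over$n > 0] == 0))
  expect_equal(over$median_ratio[over$scheme == "overall"], 1.2)
  # mixed: half the routes within the margin, half far outside
  pred <- obs
  off <- which(!is.na(obs))
  pred[off[seq(1, 30, by = 2)]] <- obs[off[seq(1, 30, by = 2)]] * 1.05
  pred[off[seq(2, 30, by = 2)]] <- obs[off[seq(2, 30, by = 2)]] * 3
  mixed <- ratio_accuracy(pred, obs)
  expect_equal(mixed$accuracy[1], 0.5)
  # invariance under common rescaling of both matrices
  resc <- ratio_accuracy(7 * pred, 7 * obs)
  expect_equal(resc$accuracy, mixed$accuracy)
  expect_equal(resc$median_ratio, mixed$median_ratio)
  expect_error(ratio_accuracy(pred, obs, margin = 0), "margin")
})

test_that("zero-observation routes are excluded from ratios and counted", {
  obs <- matrix(c(NA, 0, 10, NA), 2, 2, byrow = TRUE)
  pred <- matrix(2, 2, 2)
  out <- ratio_accuracy(pred, obs)
  expect_equal(out$n, 1L)
  expect_equal(out$n_zero_obs, 1L)
  expect_equal(out$median_ratio, 0.2)
})

test_that("model ranking sorts by DIC with a parameter-count tie-break", {
  fake <- function(model, dic, n_params, p_d = 2) {
    structure(list(model = model, dic = dic, p_d = p_d,
                   n_params = as.integer(n_params),
                   n_pairs = 30L, obs_total = 1000), class = "gravity_fit")
  }
  tab <- rank_models(list(a = fake("a", 5, 4), b = fake("b", 3, 13)))
  expect_equal(tab$model, c("b", "a"))
  expect_equal(tab$rank, 1:2)
  # equal DIC: fewer parameters first
  tie <- rank_models(list(big = fake("big", 7, 13), small = fake("small", 7, 4)))
  expect_equal(tie$model, c("small", "big"))
  # five models against a sort oracle
  set.seed(17)
  dics <- sample(seq(10, 50, by = 10))
  fits <- lapply(seq_along(dics), function(i) fake(paste0("m", i), dics[i], i))
  names(fits) <- paste0("m", seq_along(dics))
  tab5 <- rank_models(fits)
  expect_equal(tab5$dic, sort(dics))
  expect_setequal(tab5$model, names(fits))
  # percent change against a fit named basic
  wb <- rank_models(list(basic = fake("basic", 100, 4), alt = fake("alt", 59, 13)))
  expect_equal(wb$pct_change_vs_basic[wb$model == "alt"], 41)
  # mismatched data refuse to rank
  bad <- fake("bad", 1, 4); bad$obs_total <- 99
  expect_error(rank_models(list(a = fake("a", 5, 4), bad = bad)), "same observed")
})

test_that("evaluation report bundles rankings, accuracy and proportions", {
  sc <- make_benchmark_suite(seed = 3)$basic
  ctl <- mcmc_control(chains = 2, burn_in = 300, samples = 200, thin = 1, seed = 21)
  fits <- list(
    basic = fit_gravity(sc$trips, sc$geography, sc$typology, "basic", "power", ctl),
    radiation = fit_radiation(sc$trips, sc$geography, "bayes", ctl))
  rep <- evaluate_models(fits, sc$trips, sc$geography, sc$typology)
  expect_s3_class(rep, "od_evaluation")
  expect_equal(sort(rep$dic_table$model), c("basic", "radiation"))
  expect_equal(rep$dic_table$pct_change_vs_basic[rep$dic_table$model == "basic"], 0)
  expect_setequal(names(rep$proportions), c("observed", "basic", "radiation"))
  expect_output(print(rep), "Model comparison")
  dir <- withr::local_tempdir()
  write_evaluation(rep, dir)
  expect_true(file.exists(file.path(dir, "dic_table.csv")))
  expect_true(file.exists(file.path(dir, "accuracy.csv")))
  expect_true(file.exists(file.path(dir, "proportions_observed.csv")))
  expect_true(file.exists(file.path(dir, "report.json")))
})
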