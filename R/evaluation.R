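# Model comparison: DIC ranking tables, percent change from the basic model,
# predicted/observed ratio distributions by trip type, accuracy within a
# +/-10% margin, and row-normalized OD proportion matrices.

#' Row-normalized origin-destination proportions
#'
#' Divides each origin's row by its total outgoing trips, giving the
#' proportion of that origin's travel made to each destination. Rows with a
#' zero (or all-missing) total are returned as `NA` and flagged in the
#' `"zero_rows"` attribute.
#'
#' @param trips Non-negative trip matrix (`NA` diagonal allowed).
#' @return Matrix of the same shape; each defined row sums to 1.
#' @export
od_proportions <- function(trips) {
  trips <- as.matrix(trips)
  off <- row(trips) != col(trips)
  if (any(trips[off] < 0, na.rm = TRUE))
    stop("trip counts must be non-negative", call. = FALSE)
  rs <- rowSums(trips, na.rm = TRUE)
  out <- trips / rs
  zero <- rs == 0
  if (any(zero)) {
    out[zero, ] <- NA_real_
    message(sum(zero), " origin row(s) had no trips; proportions undefined")
  }
  attr(out, "zero_rows") <- which(zero)
  out
}

#' Percent change in DIC relative to the basic model
#'
#' `100 * (dic_basic - dic_model) / dic_basic`: positive values are
#' improvements over the basic model, negative values degradations.
#'
#' @param dic_model DIC of the model under comparison.
#' @param dic_basic DIC of the basic gravity model (non-zero).
#' @return Percent change (numeric).
#' @examples
#' percent_change_dic(59, 100)   # 41: a 41% improvement
#' percent_change_dic(180, 100)  # -80: worse than basic
#' @export
percent_change_dic <- function(dic_model, dic_basic) {
  if (any(dic_basic == 0)) stop("dic_basic must be non-zero", call. = FALSE)
  100 * (dic_basic - dic_model) / dic_basic
}

#' Ratio and accuracy of predictions by trip type
#'
#' For every trip category (and overall) computes the distribution of the
#' ratio of predicted to observed counts and the proportion of routes whose
#' prediction falls within `margin` of the observation
#' (`|pred/obs - 1| <= margin`). Routes with an observed count of zero have
#' an undefined ratio; they are excluded and counted in `n_zero_obs`.
#'
#' @param pred Predicted trip matrix.
#' @param obs Observed trip matrix.
#' @param typology Optional [trip_typology()]; when supplied the table covers
#'   overall plus every urbanicity (k), regional (m) and cross (n) category.
#' @param margin Relative margin, default 0.10.
#' @return Data frame with columns `scheme`, `category`, `n`, `n_zero_obs`,
#'   `median_ratio`, `ratio_q025`, `ratio_q25`, `ratio_q75`, `ratio_q975`,
#'   `accuracy`.
#' @export
ratio_accuracy <- function(pred, obs, typology = NULL, margin = 0.10) {
  if (length(margin) != 1L || !is.finite(margin) || margin <= 0)
    stop("margin must be a single positive number", call. = FALSE)
  pred <- as.matrix(pred); obs <- as.matrix(obs)
  if (!all(dim(pred) == dim(obs)))
    stop("pred and obs must have matching dimensions", call. = FALSE)
  off <- which(row(obs) != col(obs) & !is.na(obs) & !is.na(pred))
  one_row <- function(scheme, category, idx) {
    m <- obs[idx]; p <- pred[idx]
    zero <- m == 0
    r <- p[!zero] / m[!zero]
    q <- if (length(r)) stats::quantile(r, c(0.025, 0.25, 0.5, 0.75, 0.975))
         else rep(NA_real_, 5)
    data.frame(scheme = scheme, category = category,
               n = length(r), n_zero_obs = sum(zero),
               median_ratio = q[[3]], ratio_q025 = q[[1]], ratio_q25 = q[[2]],
               ratio_q75 = q[[4]], ratio_q975 = q[[5]],
               accuracy = if (length(r)) mean(abs(r - 1) <= margin) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- one_row("overall", "all", off)
  if (!is.null(typology)) {
    for (sc in c("urbanicity", "regional", "regional_urbanicity")) {
      cm <- .category_matrix(typology, sc)
      labs <- category_labels(sc)
      for (c_ in seq_along(labs)) {
        idx <- off[cm[off] == c_]
        out <- rbind(out, one_row(sc, labs[c_], idx))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Rank fitted models by DIC
#'
#' Orders fits by ascending DIC (best first); ties are broken in favour of
#' the model with fewer parameters. All fits must be to the same data
#' (checked via route count and observed total).
#'
#' @param fits Named list of `gravity_fit` / `radiation_fit` objects.
#' @return Data frame `model, dic, p_d, n_params, rank`, ordered by rank,
#'   plus `pct_change_vs_basic` when a fit named `"basic"` is present.
#' @export
rank_models <- function(fits) {
  if (length(fits) < 2L) stop("at least two fits are required", call. = FALSE)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, function(f) f$model, "")
  np <- vapply(fits, function(f) f$n_pairs, 0L)
  ot <- vapply(fits, function(f) f$obs_total, 0)
  if (length(unique(np)) > 1L || length(unique(ot)) > 1L)
    stop("fits were not made to the same observed data", call. = FALSE)
  tab <- data.frame(model = names(fits),
                    dic = vapply(fits, function(f) f$dic, 0),
                    p_d = vapply(fits, function(f) f$p_d, 0),
                    n_params = vapply(fits, function(f) f$n_params, 0L),
                    stringsAsFactors = FALSE)
  ord <- order(tab$dic, tab$n_params)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  if ("basic" %in% tab$model)
    tab$pct_change_vs_basic <-
      percent_change_dic(tab$dic, tab$dic[tab$model == "basic"])
  rownames(tab) <- NULL
  tab
}

#' Full evaluation report for a set of fitted models
#'
#' Bundles the DIC ranking table (with percent change versus the basic
#' model), per-model per-trip-type ratio/accuracy tables, and row-normalized
#' OD proportion matrices for the observation and every model.
#'
#' @param fits Named list of fits on the same observed data.
#' @param obs Observed trip matrix.
#' @param geo A [geography()].
#' @param typology Optional [trip_typology()].
#' @param margin Accuracy margin, default 0.10.
#' @return Object of class `"od_evaluation"`: `dic_table`, `accuracy`
#'   (long data frame with a `model` column), `proportions` (list of
#'   matrices incl. `observed`), `margin`.
#' @export
evaluate_models <- function(fits, obs, geo, typology = NULL, margin = 0.10) {
  if (is.null(typology)) typology <- trip_typology(geo)
  obs <- .validate_trips(obs, geo$districts$id)
  dic_table <- if (length(fits) >= 2L) rank_models(fits) else {
    f <- fits[[1]]
    data.frame(model = names(fits), dic = f$dic, p_d = f$p_d,
               n_params = f$n_params, rank = 1L,
               pct_change_vs_basic = if (identical(names(fits), "basic")) 0 else NA_real_,
               stringsAsFactors = FALSE)
  }
  acc <- list()
  props <- list(observed = od_proportions(obs))
  for (nm in names(fits)) {
    pr <- predict(fits[[nm]], geo)
    a <- ratio_accuracy(pr, obs, typology, margin)
    a$model <- nm
    acc[[nm]] <- a
    props[[nm]] <- od_proportions(pr)
  }
  structure(list(dic_table = dic_table,
                 accuracy = do.call(rbind, c(acc, list(make.row.names = FALSE))),
                 proportions = props, margin = margin),
            class = "od_evaluation")
}

#' @export
print.od_evaluation <- function(x, ...) {
  cat("Model comparison (", nrow(x$dic_table), " models)\n", sep = "")
  print(x$dic_table, row.names = FALSE, digits = 6)
  ov <- x$accuracy[x$accuracy$scheme == "overall", ]
  cat("\nOverall accuracy within +/-", 100 * x$margin, "% of observed:\n", sep = "")
  print(ov[, c("model", "n", "median_ratio", "accuracy")], row.names = FALSE,
        digits = 4)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' `dic_table.csv`, `accuracy.csv`, one `proportions_<model>.csv` per matrix,
#' and `report.json` with the tables embedded.
#'
#' @param report An [evaluate_models()] result.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_evaluation <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$dic_table, file.path(dir, "dic_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$accuracy, file.path(dir, "accuracy.csv"),
                   row.names = FALSE)
  for (nm in names(report$proportions)) {
    m <- report$proportions[[nm]]
    utils::write.csv(data.frame(origin_id = rownames(m), m, check.names = FALSE),
                     file.path(dir, paste0("proportions_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(dic_table = report$dic_table,
                            accuracy = report$accuracy,
                            margin = report$margin),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(dir)
}

#' Heatmap of an OD proportion matrix
#'
#' Simple `image()`-based rendering with origins on the y axis (top-down) and
#' destinations on the x axis, darker cells marking destinations that receive
#' a larger share of an origin's trips.
#'
#' @param prop A matrix from [od_proportions()].
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
od_heatmap <- function(prop, main = "OD proportions", ...) {
  m <- as.matrix(prop)
  m[is.na(m)] <- 0
  n <- nrow(m)
  pal <- grDevices::colorRampPalette(c("white", "lightblue", "darkblue"))(64)
  graphics::image(seq_len(ncol(m)), seq_len(n), t(m[n:1, , drop = FALSE]),
                  col = pal, xlab = "destination", ylab = "origin",
                  main = main, axes = FALSE, ...)
  graphics::box()
  invisible(prop)
}
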