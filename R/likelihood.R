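# Poisson likelihood shared by every model: m_ij ~ Pois(T_ij).

#' Poisson log-likelihood of an observed trip matrix
#'
#' `sum over routes of m * log(T) - T - log(m!)`, taken over ordered pairs
#' that are off-diagonal and observed (structurally missing routes, `NA`, are
#' excluded; observed zeros are retained and inform the likelihood).
#'
#' @param pred Predicted trip matrix (positive where `obs > 0`).
#' @param obs Observed counts (non-negative integers; matching dimensions).
#' @return The log-likelihood (scalar). `-Inf` with a warning if a positive
#'   count has predicted mean zero.
#' @export
poisson_log_likelihood <- function(pred, obs) {
  pred <- as.matrix(pred); obs <- as.matrix(obs)
  if (!all(dim(pred) == dim(obs)))
    stop("pred and obs must have matching dimensions", call. = FALSE)
  if (!is.null(rownames(pred)) && !is.null(rownames(obs)) &&
      all(rownames(obs) %in% rownames(pred)))
    pred <- pred[rownames(obs), colnames(obs), drop = FALSE]
  keep <- which(row(obs) != col(obs) & !is.na(obs) & !is.na(pred))
  m <- obs[keep]; mu <- pred[keep]
  if (any(m < 0)) stop("observed counts must be non-negative", call. = FALSE)
  if (any(mu < 0)) stop("predicted counts must be non-negative", call. = FALSE)
  if (any(mu == 0 & m > 0)) {
    warning("predicted mean is zero where a positive count was observed; log-likelihood is -Inf")
    return(-Inf)
  }
  pos <- mu > 0
  sum(m[pos] * log(mu[pos]) - mu[pos] - lfactorial(m[pos]))
}
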