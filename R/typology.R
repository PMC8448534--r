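# Trip typologies: every ordered origin-destination pair is assigned a
# category under three stratification schemes — urbanicity of the endpoints
# (k = 1..4), intra/inter-regional (m = 1..2), and their cross (n = 1..8).

.SCHEMES <- c(basic = 1L, urbanicity = 4L, regional = 2L, regional_urbanicity = 8L)

.K_LABELS <- c("rural-rural", "rural-urban", "urban-rural", "urban-urban")
.M_LABELS <- c("intra-regional", "inter-regional")
.N_LABELS <- as.vector(t(outer(.M_LABELS, .K_LABELS, paste, sep = " ")))

#' Number of trip categories of a stratification scheme
#'
#' @param scheme One of `"basic"`, `"urbanicity"`, `"regional"`,
#'   `"regional_urbanicity"`.
#' @return Integer category count (1, 4, 2 or 8).
#' @export
n_categories <- function(scheme) {
  scheme <- match.arg(scheme, names(.SCHEMES))
  .SCHEMES[[scheme]]
}

#' Category labels of a stratification scheme
#'
#' @inheritParams n_categories
#' @return Character vector of category names in index order.
#' @export
category_labels <- function(scheme) {
  switch(match.arg(scheme, names(.SCHEMES)),
         basic = "all", urbanicity = .K_LABELS, regional = .M_LABELS,
         regional_urbanicity = .N_LABELS)
}

#' Per-pair trip categories
#'
#' `classify_urbanicity_pair()` returns the urbanicity category
#' k = 1 (rural to rural), 2 (rural to urban), 3 (urban to rural),
#' 4 (urban to urban). `classify_region_pair()` returns m = 1 for
#' intra-regional pairs and 2 for inter-regional. The combined index is
#' n = 4(m - 1) + k, enumerating intra-regional categories 1-4 and
#' inter-regional 5-8 in the same urbanicity order. All are vectorised.
#'
#' @param urbanicity_i,urbanicity_j Urbanicity labels (`"urban"`/`"rural"`)
#'   of origin and destination.
#' @param region_i,region_j Region ids of origin and destination.
#' @return Integer category indices.
#' @export
classify_urbanicity_pair <- function(urbanicity_i, urbanicity_j) {
  ok <- c("rural", "urban")
  if (any(!urbanicity_i %in% ok) || any(!urbanicity_j %in% ok))
    stop("urbanicity labels must be 'urban' or 'rural'", call. = FALSE)
  1L + 2L * (urbanicity_i == "urban") + 1L * (urbanicity_j == "urban")
}

#' @rdname classify_urbanicity_pair
#' @export
classify_region_pair <- function(region_i, region_j) {
  if (any(is.na(region_i)) || any(is.na(region_j)))
    stop("region ids must not be missing", call. = FALSE)
  ifelse(region_i == region_j, 1L, 2L)
}

#' @rdname classify_urbanicity_pair
#' @export
classify_region_urbanicity_pair <- function(region_i, region_j,
                                            urbanicity_i, urbanicity_j) {
  4L * (classify_region_pair(region_i, region_j) - 1L) +
    classify_urbanicity_pair(urbanicity_i, urbanicity_j)
}

#' Trip typology of a geography
#'
#' Computes, for every ordered origin-destination pair, the category index
#' under each stratification scheme. The diagonal (within-district travel) is
#' `NA` throughout.
#'
#' @param geo A [geography()].
#' @return An object of class `"trip_typology"`: list with integer matrices
#'   `k` (urbanicity, 1..4), `m` (regional, 1..2), `n` (cross, 1..8), the
#'   district `ids`, and `labels` documenting the index ordering.
#' @export
trip_typology <- function(geo) {
  stopifnot(inherits(geo, "geography"))
  dd <- geo$districts
  if (any(is.na(dd$urbanicity)) || any(is.na(dd$region_id)))
    stop("districts must carry urbanicity and region_id", call. = FALSE)
  n <- nrow(dd)
  oi <- rep(seq_len(n), times = n)   # row index = origin
  dj <- rep(seq_len(n), each = n)    # col index = destination
  mk <- function(x) matrix(x, n, n, dimnames = list(dd$id, dd$id))
  k <- mk(classify_urbanicity_pair(dd$urbanicity[oi], dd$urbanicity[dj]))
  m <- mk(classify_region_pair(dd$region_id[oi], dd$region_id[dj]))
  nn <- 4L * (m - 1L) + k
  diag(k) <- diag(m) <- diag(nn) <- NA_integer_
  structure(
    list(k = k, m = m, n = nn, ids = dd$id,
         labels = list(k = .K_LABELS, m = .M_LABELS, n = .N_LABELS)),
    class = "trip_typology"
  )
}

# per-pair category matrix for a scheme (basic = all ones)
.category_matrix <- function(typology, scheme) {
  scheme <- match.arg(scheme, names(.SCHEMES))
  if (scheme == "basic") {
    out <- typology$k
    out[!is.na(out)] <- 1L
    return(out)
  }
  typology[[switch(scheme, urbanicity = "k", regional = "m",
                   regional_urbanicity = "n")]]
}

#' @export
print.trip_typology <- function(x, ...) {
  cat("Trip typology over", length(x$ids), "districts",
      sprintf("(%d ordered pairs)\n", length(x$ids) * (length(x$ids) - 1L)))
  off <- row(x$n) != col(x$n)
  tab <- table(factor(x$n[off], levels = 1:8, labels = x$labels$n))
  print(tab)
  invisible(x)
}

#' @export
as.data.frame.trip_typology <- function(x, ...) {
  n <- length(x$ids)
  keep <- which(row(x$k) != col(x$k))
  data.frame(origin_id = x$ids[row(x$k)[keep]],
             dest_id = x$ids[col(x$k)[keep]],
             k = x$k[keep], m = x$m[keep], n = x$n[keep],
             stringsAsFactors = FALSE)
}

#' Write a trip typology to CSV
#'
#' Columns `origin_id,dest_id,k,m,n`; the file is preceded by comment lines
#' declaring the category ordering.
#'
#' @param typology A [trip_typology()].
#' @param path Output path.
#' @export
write_typology <- function(typology, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# k: ", paste(sprintf("%d=%s", 1:4, typology$labels$k), collapse = "; ")),
    paste0("# m: ", paste(sprintf("%d=%s", 1:2, typology$labels$m), collapse = "; ")),
    "# n = 4*(m-1) + k"
  ), con)
  utils::write.csv(as.data.frame(typology), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
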