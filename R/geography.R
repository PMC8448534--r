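# Districts, urbanicity classification, haversine distance matrices, and
# aggregation to coarser administrative units.

#' Great-circle distance between points (haversine)
#'
#' Distance on a sphere of radius 6371.0 km between points given in decimal
#' degrees. Vectorised over all four arguments.
#'
#' @param lat1,lon1 Latitude and longitude of the first point, decimal degrees.
#' @param lat2,lon2 Latitude and longitude of the second point.
#' @return Distance in kilometres (numeric, `>= 0`).
#' @examples
#' haversine_distance(0, 0, 0, 1)  # one degree of arc at the equator
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1, "point 1")
  .check_coords(lat2, lon2, "point 2")
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad / 2
  dlam <- (lon2 - lon1) * rad / 2
  a <- sin(dphi)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam)^2
  # guard rounding just above 1 for antipodal points
  2 * 6371.0 * asin(sqrt(pmin(a, 1)))
}

.check_coords <- function(lat, lon, what) {
  if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90))
    stop(what, ": latitude must be finite and in [-90, 90]", call. = FALSE)
  if (any(!is.finite(lon)) || any(lon < -180) || any(lon > 180))
    stop(what, ": longitude must be finite and in [-180, 180]", call. = FALSE)
  invisible(TRUE)
}

#' Classify a district as urban or rural
#'
#' A district is labelled `"urban"` when its fraction of urban grid cells
#' strictly exceeds the threshold, `"rural"` otherwise (ties go to rural).
#' The conventional threshold is 0.5; 0.1 is a common sensitivity setting.
#'
#' @param urban_fraction Proportion of urban grid cells, in `[0, 1]`. Vectorised.
#' @param threshold Classification threshold in `[0, 1]`.
#' @return Character vector in `{"urban", "rural"}`.
#' @export
classify_urbanicity <- function(urban_fraction, threshold = 0.5) {
  if (any(!is.finite(urban_fraction)) || any(urban_fraction < 0) || any(urban_fraction > 1))
    stop("urban_fraction must be in [0, 1]", call. = FALSE)
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]", call. = FALSE)
  ifelse(urban_fraction > threshold, "urban", "rural")
}

.validate_districts <- function(districts) {
  need <- c("id", "name", "region_id", "population", "lat", "lon", "urban_fraction")
  miss <- setdiff(need, names(districts))
  if (length(miss))
    stop("district table is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  districts$id <- as.character(districts$id)
  districts$region_id <- as.character(districts$region_id)
  dup <- unique(districts$id[duplicated(districts$id)])
  if (length(dup))
    stop("duplicate district ids: ", paste(dup, collapse = ", "), call. = FALSE)
  if (nrow(districts) < 2L)
    stop("at least 2 districts are required", call. = FALSE)
  if (any(!is.finite(districts$population)) || any(districts$population <= 0))
    stop("population must be positive and finite for every district", call. = FALSE)
  .check_coords(districts$lat, districts$lon, "district centroid")
  if (any(!is.finite(districts$urban_fraction)) ||
      any(districts$urban_fraction < 0) || any(districts$urban_fraction > 1))
    stop("urban_fraction must be in [0, 1] for every district", call. = FALSE)
  districts
}

#' Build a geography from a district table
#'
#' Assembles the spatial backbone of the analysis: the district table (with
#' derived urbanicity labels), the symmetric haversine distance matrix between
#' district centroids, and the total population.
#'
#' @param districts A data frame with columns
#'   `id, name, region_id, population, lat, lon, urban_fraction`. Input row
#'   order is retained.
#' @param urban_threshold Urbanicity threshold passed to
#'   [classify_urbanicity()].
#' @return An object of class `"geography"`: a list with elements
#'   `districts` (data frame incl. `urbanicity`), `distance` (km, symmetric,
#'   zero diagonal, dimnames = district ids), `total_population`, and
#'   `urban_threshold`.
#' @seealso [read_districts()], [aggregate_geography()], [trip_typology()]
#' @export
geography <- function(districts, urban_threshold = 0.5) {
  districts <- .validate_districts(as.data.frame(districts))
  districts$urbanicity <- classify_urbanicity(districts$urban_fraction, urban_threshold)
  n <- nrow(districts)
  d <- haversine_distance(
    districts$lat[rep(seq_len(n), each = n)],
    districts$lon[rep(seq_len(n), each = n)],
    districts$lat[rep(seq_len(n), times = n)],
    districts$lon[rep(seq_len(n), times = n)]
  )
  d <- matrix(d, n, n, byrow = TRUE, dimnames = list(districts$id, districts$id))
  d <- (d + t(d)) / 2          # enforce exact symmetry
  diag(d) <- 0
  structure(
    list(districts = districts, distance = d,
         total_population = sum(districts$population),
         urban_threshold = urban_threshold),
    class = "geography"
  )
}

#' @export
print.geography <- function(x, ...) {
  dd <- x$districts
  cat("Geography:", nrow(dd), "districts in", length(unique(dd$region_id)),
      "regions\n")
  cat("  total population:", format(x$total_population, big.mark = ","), "\n")
  cat("  urban districts: ", sum(dd$urbanicity == "urban"), " (threshold ",
      x$urban_threshold, ")\n", sep = "")
  cat("  centroid distances: ",
      round(min(x$distance[upper.tri(x$distance)]), 1), "-",
      round(max(x$distance), 1), " km\n", sep = "")
  invisible(x)
}

#' Read / write a district table
#'
#' CSV with header `id,name,region_id,population,lat,lon,urban_fraction`
#' (UTF-8, decimal point).
#'
#' @param path File path.
#' @return `read_districts()` returns the district data frame.
#' @export
read_districts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .validate_districts(d)
}

#' @rdname read_districts
#' @param districts District table (or the `districts` element of a geography).
#' @export
write_districts <- function(districts, path) {
  if (inherits(districts, "geography")) districts <- districts$districts
  cols <- c("id", "name", "region_id", "population", "lat", "lon", "urban_fraction")
  utils::write.csv(districts[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read districts from GeoJSON polygons
#'
#' Reduces each Polygon/MultiPolygon feature to its area centroid (standard
#' shoelace centroid of the outer ring, largest ring for multipolygons).
#' Feature properties must carry `id, name, region_id, population,
#' urban_fraction`.
#'
#' @param path Path to a GeoJSON FeatureCollection.
#' @return A district data frame suitable for [geography()].
#' @export
read_districts_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  rows <- lapply(gj$features, function(f) {
    p <- f$properties
    ring <- .outer_ring(f$geometry)
    cen <- .polygon_centroid(ring)
    data.frame(id = as.character(p$id), name = as.character(p$name),
               region_id = as.character(p$region_id),
               population = as.numeric(p$population),
               lat = cen[2], lon = cen[1],
               urban_fraction = as.numeric(p$urban_fraction),
               stringsAsFactors = FALSE)
  })
  .validate_districts(do.call(rbind, rows))
}

.outer_ring <- function(geometry) {
  type <- geometry$type
  if (identical(type, "Polygon")) {
    ring <- geometry$coordinates[[1]]
  } else if (identical(type, "MultiPolygon")) {
    rings <- lapply(geometry$coordinates, `[[`, 1)
    areas <- vapply(rings, function(r) abs(.shoelace(.ring_matrix(r))), numeric(1))
    ring <- rings[[which.max(areas)]]
  } else {
    stop("unsupported geometry type: ", type, call. = FALSE)
  }
  .ring_matrix(ring)
}

.ring_matrix <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  storage.mode(m) <- "double"
  m
}

.shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

# standard polygon (area) centroid, planar in lon/lat — adequate for
# district-sized polygons
.polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  cross <- x * y[i2] - x[i2] * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x[i2]) * cross) / (6 * a), sum((y + y[i2]) * cross) / (6 * a))
}

#' Aggregate a geography (and trip matrix) to coarser units
#'
#' Groups districts into larger units, e.g. to study sensitivity to the
#' modifiable areal unit problem by re-fitting models at a coarser
#' administrative level. Unit population is the sum of member populations;
#' unit centroid and urban fraction are population-weighted means; the unit
#' region id is taken from the most populous member. Unit-level trips are the
#' sums of member-pair trips, with trips that become within-unit dropped
#' (the diagonal is never modelled).
#'
#' @param geo A [geography()].
#' @param mapping Named character vector mapping every district id to a unit
#'   id (names = district ids).
#' @param trips Optional trip matrix aligned with `geo` (ids as dimnames).
#' @return A list with elements `geography` (units in order of first
#'   appearance in `mapping`) and `trips` (aggregated matrix, or `NULL`).
#' @export
aggregate_geography <- function(geo, mapping, trips = NULL) {
  stopifnot(inherits(geo, "geography"))
  dd <- geo$districts
  miss <- setdiff(dd$id, names(mapping))
  if (length(miss))
    stop("mapping is missing districts: ", paste(miss, collapse = ", "), call. = FALSE)
  unit <- as.character(mapping[dd$id])
  units <- unique(unit)
  agg <- do.call(rbind, lapply(units, function(u) {
    m <- dd[unit == u, , drop = FALSE]
    w <- m$population / sum(m$population)
    data.frame(id = u, name = u,
               region_id = m$region_id[which.max(m$population)],
               population = sum(m$population),
               lat = sum(w * m$lat), lon = sum(w * m$lon),
               urban_fraction = sum(w * m$urban_fraction),
               stringsAsFactors = FALSE)
  }))
  out_geo <- if (nrow(agg) >= 2L) geography(agg, geo$urban_threshold) else {
    # degenerate single-unit aggregation: still return the table
    agg$urbanicity <- classify_urbanicity(agg$urban_fraction, geo$urban_threshold)
    structure(list(districts = agg,
                   distance = matrix(0, 1, 1, dimnames = list(agg$id, agg$id)),
                   total_population = sum(agg$population),
                   urban_threshold = geo$urban_threshold),
              class = "geography")
  }
  out_trips <- NULL
  if (!is.null(trips)) {
    trips <- .validate_trips(trips, dd$id)
    G <- outer(unit, units, "==") * 1
    tt <- trips
    tt[is.na(tt)] <- 0
    out_trips <- t(G) %*% tt %*% G
    dimnames(out_trips) <- list(units, units)
    diag(out_trips) <- NA_real_
  }
  list(geography = out_geo, trips = out_trips)
}

# ---- trip matrices -----------------------------------------------------------

.validate_trips <- function(trips, ids = NULL, allow_na = TRUE) {
  trips <- as.matrix(trips)
  if (nrow(trips) != ncol(trips))
    stop("trip matrix must be square", call. = FALSE)
  if (!is.null(ids)) {
    if (is.null(rownames(trips))) {
      if (nrow(trips) != length(ids))
        stop("trip matrix dimension does not match the geography", call. = FALSE)
      dimnames(trips) <- list(ids, ids)
    } else {
      if (!setequal(rownames(trips), ids))
        stop("trip matrix ids do not match the geography", call. = FALSE)
      trips <- trips[ids, ids]
    }
  }
  off <- trips[row(trips) != col(trips)]
  if (any(off < 0, na.rm = TRUE))
    stop("trip counts must be non-negative", call. = FALSE)
  diag(trips) <- NA_real_
  trips
}

#' Read / write an origin-destination trip matrix
#'
#' Long form CSV has columns `origin_id,dest_id,trips`; wide form has a first
#' column of origin ids and one column per destination id. Routes absent from
#' a long-form file are structurally missing (`NA`), distinct from observed
#' zeros; the diagonal is always `NA` (within-district travel is not
#' modelled).
#'
#' @param path File path.
#' @param ids Optional district ids fixing the matrix order.
#' @return `read_trips()` returns a square numeric matrix with id dimnames.
#' @export
read_trips <- function(path, ids = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (all(c("origin_id", "dest_id", "trips") %in% names(d))) {
    all_ids <- if (is.null(ids)) unique(c(d$origin_id, d$dest_id)) else ids
    m <- matrix(NA_real_, length(all_ids), length(all_ids),
                dimnames = list(all_ids, all_ids))
    m[cbind(match(as.character(d$origin_id), all_ids),
            match(as.character(d$dest_id), all_ids))] <- d$trips
  } else {
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- as.character(d[[1]])
    colnames(m) <- names(d)[-1]
  }
  .validate_trips(m, ids)
}

#' @rdname read_trips
#' @param trips Trip matrix.
#' @param format `"long"` (default; omits structurally missing routes) or
#'   `"wide"`.
#' @export
write_trips <- function(trips, path, format = c("long", "wide")) {
  format <- match.arg(format)
  trips <- .validate_trips(trips)
  if (format == "long") {
    keep <- which(row(trips) != col(trips) & !is.na(trips))
    d <- data.frame(origin_id = rownames(trips)[row(trips)[keep]],
                    dest_id = colnames(trips)[col(trips)[keep]],
                    trips = trips[keep])
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    d <- data.frame(origin_id = rownames(trips), trips, check.names = FALSE)
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Drop districts with no observed trips
#'
#' Districts whose observed row and column are entirely missing (as happens
#' when a provider supplies no data for a district) cannot inform a fit and
#' are removed before modelling, with a message naming them.
#'
#' @param trips Observed trip matrix.
#' @param geo The matching [geography()].
#' @return List with elements `trips`, `geography`, and `dropped` (ids).
#' @export
drop_missing_districts <- function(trips, geo) {
  trips <- .validate_trips(trips, geo$districts$id)
  off <- row(trips) != col(trips)
  dead <- vapply(seq_len(nrow(trips)), function(i) {
    all(is.na(trips[i, ][off[i, ]])) && all(is.na(trips[, i][off[, i]]))
  }, logical(1))
  if (!any(dead)) return(list(trips = trips, geography = geo, dropped = character(0)))
  keep <- !dead
  ids <- geo$districts$id[keep]
  message("dropping districts with no trip data: ",
          paste(geo$districts$id[dead], collapse = ", "))
  list(trips = trips[ids, ids],
       geography = geography(geo$districts[keep, , drop = FALSE], geo$urban_threshold),
       dropped = geo$districts$id[dead])
}
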