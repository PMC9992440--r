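# reduce backtrack ensembles to metrics and partition into sub-origins

#' Per-simulation trajectory metrics
#'
#' Ensemble means with 95% confidence intervals (mean +/- 1.96 sd/sqrt(n))
#' of the per-particle distance travelled and of the origin (endpoint)
#' latitude, plus the mean origin longitude.
#'
#' @param result A `backtrack_result` (>= 2 particles), or a list of them.
#' @param id Optional simulation identifier; defaults to the collection
#'   date (or launch year-day).
#' @return One-row data frame (or row-bound data frame for a list) with
#'   columns `id, date, mean_distance_km, dist_lo, dist_hi,
#'   mean_origin_lat, lat_lo, lat_hi, mean_origin_lon, n_particles`.
#' @export
compute_track_metrics <- function(result, id = NULL) {
  if (!inherits(result, "backtrack_result") && is.list(result)) {
    out <- do.call(rbind, lapply(seq_along(result), function(k)
      compute_track_metrics(result[[k]],
                            id = if (!is.null(names(result))) names(result)[k] else k)))
    rownames(out) <- NULL
    return(out)
  }
  n <- nrow(result$endpoints)
  if (n < 2) stop("confidence intervals need at least 2 particles")
  ci <- function(x) 1.96 * stats::sd(x) / sqrt(length(x))
  d <- result$cum_dist_km
  la <- result$endpoints[, "lat"]
  data.frame(
    id = as.character(id %||% (result$date %||% result$yearday)),
    date = if (!is.null(result$date)) result$date else as.Date(NA),
    mean_distance_km = mean(d),
    dist_lo = mean(d) - ci(d), dist_hi = mean(d) + ci(d),
    mean_origin_lat = mean(la),
    lat_lo = mean(la) - ci(la), lat_hi = mean(la) + ci(la),
    mean_origin_lon = mean(result$endpoints[, "lon"]),
    n_particles = n)
}

#' K-means partitioning of simulations into sub-origin groups
#'
#' Clusters simulations on z-standardized (mean distance travelled, mean
#' origin latitude), best of `nstart` restarts by total within-cluster sum
#' of squares; deterministic given `seed`.
#'
#' @param metrics Metrics data frame from [compute_track_metrics()].
#' @param k Number of clusters (default 2).
#' @param seed Integer seed.
#' @param nstart Random restarts.
#' @param standardize z-score the two features first (default `TRUE`).
#' @return A `suborigin_assignment`: list with `cluster` (integer vector
#'   named by simulation id), `centers` (in feature space used), `withinss`
#'   and the feature matrix.
#' @export
partition_kmeans <- function(metrics, k = 2, seed = 1L, nstart = 10,
                             standardize = TRUE) {
  stopifnot(nrow(metrics) >= k)
  x <- as.matrix(metrics[, c("mean_distance_km", "mean_origin_lat")])
  if (all(apply(x, 2, function(c) diff(range(c))) < 1e-12))
    stop("degenerate metrics: all simulations identical, cannot cluster")
  xs <- if (standardize) scale(x) else x
  set.seed(as.integer(seed))
  km <- stats::kmeans(xs, centers = k, nstart = nstart)
  cl <- km$cluster
  names(cl) <- metrics$id
  structure(list(cluster = cl, centers = km$centers,
                 withinss = km$tot.withinss, features = xs,
                 metrics = metrics, k = k),
            class = "suborigin_assignment")
}

#' Label sub-origin clusters as pathway A and B
#'
#' Pathway A is the cluster with the larger mean of per-simulation mean
#' distances (long meandering equatorial route); as a consistency check it
#' should also have the lower mean origin latitude. When the two criteria
#' disagree, distance wins and a warning is recorded.
#'
#' @param assignment A `suborigin_assignment` with k = 2.
#' @param metrics Metrics data frame (defaults to the one stored in the
#'   assignment).
#' @return The assignment, augmented with `label` (named "A"/"B" vector per
#'   simulation), `cluster_summary` and `criteria_agree`.
#' @export
label_suborigins <- function(assignment, metrics = assignment$metrics) {
  stopifnot(inherits(assignment, "suborigin_assignment"))
  if (assignment$k != 2) stop("labelling requires exactly two clusters")
  cl <- assignment$cluster[as.character(metrics$id)]
  md <- tapply(metrics$mean_distance_km, cl, mean)
  ml <- tapply(metrics$mean_origin_lat, cl, mean)
  a_by_dist <- names(md)[which.max(md)]
  a_by_lat <- names(ml)[which.min(ml)]
  agree <- identical(a_by_dist, a_by_lat)
  if (!agree)
    warning("distance and origin-latitude criteria disagree; labelling by distance")
  label <- ifelse(cl == a_by_dist, "A", "B")
  names(label) <- names(cl)
  assignment$label <- label
  assignment$criteria_agree <- agree
  assignment$cluster_summary <- data.frame(
    label = ifelse(names(md) == a_by_dist, "A", "B"),
    mean_distance_km = as.numeric(md),
    mean_origin_lat = as.numeric(ml),
    n = as.integer(table(cl)[names(md)]))
  assignment
}

#' @export
print.suborigin_assignment <- function(x, ...) {
  cat(sprintf("suborigin_assignment: %d simulations in %d clusters\n",
              length(x$cluster), x$k))
  if (!is.null(x$label)) {
    print(x$cluster_summary, row.names = FALSE)
    if (!x$criteria_agree)
      cat("  note: distance and latitude criteria disagreed; labelled by distance\n")
  }
  invisible(x)
}
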