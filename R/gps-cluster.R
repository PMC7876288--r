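# Stay-point clustering: K-means over the stationary fixes, with K chosen
# as the smallest value for which every fix lies within a distance threshold
# of its centroid.

#' Cluster stationary GPS fixes into stay locations
#'
#' Runs K-means (on a local planar projection of the fixes) for K = 1, 2,
#' ... and selects the smallest K at which every stationary fix lies within
#' `max_dist_m` of its assigned centroid, capped at `k_max` (with a
#' warning). Each K uses `nstart` restarts; ties resolve to the lowest
#' within-cluster sum of squares (the `stats::kmeans` criterion).
#'
#' @param labeled data.frame from [label_states()]; only rows with
#'   `state == "stationary"` are clustered.
#' @param max_dist_m maximum tolerated fix-to-centroid distance in meters;
#'   default 500.
#' @param k_max largest K tried; default 20.
#' @param seed RNG seed for the K-means restarts.
#' @param nstart random restarts per K; default 10.
#' @return A list of class `stay_clusters`: `k`, `centroids` (data.frame
#'   lat/lon), `assignment` (cluster index per stationary row, NA for
#'   transition rows), `stationary` (logical row mask), `max_dist_m`,
#'   `capped` (TRUE if `k_max` was hit). With no stationary fixes, returns
#'   `NULL` with reason `"no_stationary_samples"` attached.
#' @export
cluster_stationary <- function(labeled, max_dist_m = 500, k_max = 20,
                               seed = 1L, nstart = 10) {
  stat <- labeled$state == "stationary"
  if (!any(stat)) {
    out <- structure(list(k = 0L, centroids = NULL, assignment = NULL,
                          stationary = stat, reason = "no_stationary_samples"),
                     class = "stay_clusters")
    return(out)
  }
  lat <- labeled$latitude[stat]
  lon <- labeled$longitude[stat]
  lat0 <- mean(lat)
  xy <- project_local_m(lat, lon, lat0)
  n_distinct <- nrow(unique(xy))
  capped <- FALSE
  fit <- NULL
  k_sel <- NA_integer_
  with_seed(seed, {
    for (k in seq_len(min(k_max, n_distinct))) {
      km <- suppressWarnings(
        stats::kmeans(xy, centers = k, nstart = nstart, iter.max = 50)
      )
      dmax <- sqrt(max(rowSums((xy - km$centers[km$cluster, , drop = FALSE])^2)))
      fit <- km
      k_sel <- k
      if (dmax <= max_dist_m) break
      if (k == min(k_max, n_distinct) && dmax > max_dist_m) {
        capped <- TRUE
      }
    }
  })
  if (capped) {
    warning("k_max = ", k_max, " reached before the ", max_dist_m,
            " m intracluster criterion was met")
  }
  # back-project centroids to lat/lon
  r <- 6371008.8
  cen_lat <- fit$centers[, "y"] / r * 180 / pi
  cen_lon <- fit$centers[, "x"] / (r * cos(lat0 * pi / 180)) * 180 / pi
  assignment <- rep(NA_integer_, nrow(labeled))
  assignment[stat] <- fit$cluster
  structure(list(
    k = k_sel,
    centroids = data.frame(latitude = cen_lat, longitude = cen_lon,
                           row.names = NULL),
    assignment = assignment,
    stationary = stat,
    max_dist_m = max_dist_m,
    capped = capped
  ), class = "stay_clusters")
}

#' @export
print.stay_clusters <- function(x, ...) {
  if (x$k == 0L) {
    cat("<stay_clusters> undefined:", x$reason, "\n")
  } else {
    cat("<stay_clusters> k =", x$k, "over", sum(x$stationary),
        "stationary fixes", if (isTRUE(x$capped)) "(k_max capped)" else "",
        "\n")
  }
  invisible(x)
}
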