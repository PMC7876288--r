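# The five location features: total distance, location variance, location
# entropy, normalized entropy, and homestay (time at home).

#' Extract mobility features over a window of study days
#'
#' Computes, over the rows of `labeled` whose `study_day` is in `window`:
#'
#' * `total_distance` (km): sum of haversine distances between consecutive
#'   samples within a segment (gaps never contribute distance).
#' * `location_variance`: `log(var(lat) + var(lon))` over stationary fixes,
#'   in raw decimal degrees; undefined with fewer than 3 stationary fixes
#'   or zero variance.
#' * `entropy` (nats): `-sum(p_i * log(p_i))` where `p_i` is the share of
#'   stationary dwell time spent in stay cluster i.
#' * `normalized_entropy`: entropy divided by `log(N)` for N clusters with
#'   dwell; 0 by convention when N = 1.
#' * `homestay`: dwell seconds in the home cluster divided by 86,400 x
#'   (number of days in the window), clipped to \[0, 1\]. The home cluster
#'   holds the most stationary fixes with local time in \[00:00, 06:00);
#'   undefined if no night-time fixes exist. Set
#'   `homestay_denominator = "tracked"` to divide by total credited dwell
#'   time instead of the full 24 h day.
#'
#' Undefined sub-features are NA with a `reason` attribute and never poison
#' the others.
#'
#' @param labeled output of [label_states()] (localized, cleaned, labeled),
#'   with a `study_day` column.
#' @param clusters a `stay_clusters` model fitted on this window's
#'   stationary fixes (see [cluster_stationary()]).
#' @param window integer vector of study days; defaults to all days present.
#' @param homestay_denominator `"day"` (86,400 s per day, the default) or
#'   `"tracked"` (total credited dwell).
#' @return A one-row data.frame with the five features plus `n_samples`,
#'   `n_stationary`, `n_clusters`; undefined entries carry reason codes in
#'   the `reasons` attribute.
#' @export
extract_mobility_features <- function(labeled, clusters,
                                      window = NULL,
                                      homestay_denominator = c("day", "tracked")) {
  homestay_denominator <- match.arg(homestay_denominator)
  if (is.null(window)) window <- unique(labeled$study_day)
  sel <- labeled$study_day %in% window
  w <- labeled[sel, , drop = FALSE]
  home_cluster <- NA_integer_
  asg <- if (!is.null(clusters$assignment)) clusters$assignment[sel] else
    rep(NA_integer_, nrow(w))
  reasons <- list()
  res <- list(total_distance = NA_real_, location_variance = NA_real_,
              entropy = NA_real_, normalized_entropy = NA_real_,
              homestay = NA_real_)

  if (nrow(w) == 0) {
    reasons <- list(total_distance = "no_samples",
                    location_variance = "no_samples", entropy = "no_samples",
                    normalized_entropy = "no_samples", homestay = "no_samples")
  } else {
    n <- nrow(w)
    # total distance: consecutive within-segment hops only
    if (n >= 2) {
      same_seg <- diff(w$segment) == 0
      d <- haversine_km(w$latitude[-n], w$longitude[-n],
                        w$latitude[-1], w$longitude[-1])
      res$total_distance <- sum(d[same_seg])
    } else {
      res$total_distance <- 0
    }

    stat <- w$state == "stationary"
    if (sum(stat) >= 3) {
      v <- stats::var(w$latitude[stat]) + stats::var(w$longitude[stat])
      if (v > 0) {
        res$location_variance <- log(v)
      } else {
        reasons$location_variance <- "zero_variance"
      }
    } else {
      reasons$location_variance <- "too_few_stationary"
    }

    # dwell-time share per stay cluster
    if (clusters$k >= 1 && any(stat & !is.na(asg))) {
      dw <- tapply(w$dwell_sec[stat], asg[stat], sum)
      dw <- dw[dw > 0]
      if (length(dw) >= 1 && sum(dw) > 0) {
        p <- as.numeric(dw) / sum(dw)
        res$entropy <- -sum(p * log(p))
        n_cl <- length(p)
        res$normalized_entropy <- if (n_cl == 1) 0 else res$entropy / log(n_cl)
      } else {
        reasons$entropy <- "no_dwell"
        reasons$normalized_entropy <- "no_dwell"
      }
      # home cluster: most stationary fixes in the [00:00, 06:00) window
      night <- stat & !is.na(asg) & w$local_sec >= 0 & w$local_sec < 6 * 3600
      if (any(night)) {
        counts <- table(asg[night])
        home <- as.integer(names(counts)[which.max(counts)])
        home_dwell <- sum(w$dwell_sec[stat & !is.na(asg) & asg == home])
        denom <- if (homestay_denominator == "day") {
          86400 * length(window)
        } else {
          sum(w$dwell_sec[stat])
        }
        if (denom > 0) {
          res$homestay <- min(max(home_dwell / denom, 0), 1)
        } else {
          reasons$homestay <- "zero_denominator"
        }
        home_cluster <- home
      } else {
        reasons$homestay <- "no_night_samples"
      }
    } else {
      reasons$entropy <- "no_cluster_model"
      reasons$normalized_entropy <- "no_cluster_model"
      reasons$homestay <- "no_cluster_model"
    }
  }
  out <- data.frame(res)
  out$n_samples <- nrow(w)
  out$n_stationary <- sum(w$state == "stationary")
  out$n_clusters <- clusters$k %||% 0L
  attr(out, "reasons") <- reasons
  attr(out, "home_cluster") <- home_cluster
  out
}

#' Location entropy from dwell shares
#'
#' The closed-form core of the entropy feature, exposed for direct use:
#' `-sum(p_i * log(p_i))` in nats over positive dwell shares, and its
#' normalization by `log(N)` (0 when N = 1).
#'
#' @param dwell numeric vector of per-cluster dwell times (any positive
#'   unit); zeros are dropped.
#' @return A list with `entropy` (nats) and `normalized_entropy`.
#' @examples
#' location_entropy(c(1, 1))      # ln 2, normalized 1
#' location_entropy(c(0.7, 0.3))  # 0.6109 nats
#' @export
location_entropy <- function(dwell) {
  stopifnot(all(dwell >= 0), sum(dwell) > 0)
  p <- dwell[dwell > 0] / sum(dwell)
  h <- -sum(p * log(p))
  list(entropy = h,
       normalized_entropy = if (length(p) == 1) 0 else h / log(length(p)))
}
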