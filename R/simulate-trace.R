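# Raw GPS trace generator: dwell segments at anchors, movement at a
# configured speed, Gaussian positional jitter, accuracy draws, and
# injected sensing artifacts (exact duplicates, (0,0) fixes, accuracy
# outliers).

#' Define a movement profile for the GPS generator
#'
#' @param home `c(lat, lon)` of the home anchor.
#' @param anchors optional data.frame of secondary anchors (`latitude`,
#'   `longitude`), 0-4 rows.
#' @param schedule optional data.frame of visits: `day` (study day),
#'   `anchor` (row index into `anchors`), `start_hour`, `end_hour`
#'   (decimal hours; the visit includes travel from/to home at
#'   `speed_kmh`). Overlapping entries within a day are rejected.
#' @param speed_kmh transition speed; default 4.5 (walking).
#' @param jitter_sd_m Gaussian positional jitter SD in meters; default 10.
#' @param interval_s sampling interval in seconds; default 60, with
#'   uniform +/-5 s timing jitter.
#' @param accuracy_meanlog,accuracy_sdlog log-normal accuracy parameters;
#'   defaults log(10) and 0.35.
#' @param dup_rate,zero_rate,outlier_rate artifact injection rates;
#'   defaults 0.
#' @param outlier_factor multiplier applied to an outlier's accuracy;
#'   default 25.
#' @return A list of class `gps_profile`.
#' @export
gps_profile <- function(home, anchors = NULL, schedule = NULL,
                        speed_kmh = 4.5, jitter_sd_m = 10, interval_s = 60,
                        accuracy_meanlog = log(10), accuracy_sdlog = 0.35,
                        dup_rate = 0, zero_rate = 0, outlier_rate = 0,
                        outlier_factor = 25) {
  stopifnot(length(home) == 2)
  if (!is.null(anchors)) stopifnot(nrow(anchors) <= 4)
  if (!is.null(schedule) && nrow(schedule)) {
    stopifnot(all(schedule$end_hour > schedule$start_hour))
    for (d in unique(schedule$day)) {
      s <- schedule[schedule$day == d, , drop = FALSE]
      s <- s[order(s$start_hour), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start_hour[-1] < s$end_hour[-nrow(s)])) {
        stop("overlapping schedule entries on day ", d)
      }
    }
  }
  structure(list(
    home = home, anchors = anchors, schedule = schedule,
    speed_kmh = speed_kmh, jitter_sd_m = jitter_sd_m,
    interval_s = interval_s, accuracy_meanlog = accuracy_meanlog,
    accuracy_sdlog = accuracy_sdlog, dup_rate = dup_rate,
    zero_rate = zero_rate, outlier_rate = outlier_rate,
    outlier_factor = outlier_factor
  ), class = "gps_profile")
}

#' Simulate a raw GPS trace from a movement profile
#'
#' Each day the participant sits at home except for scheduled visits:
#' travel to the anchor at `speed_kmh` starting at `start_hour`, dwell,
#' and travel back so as to arrive home by... (departure at `end_hour`).
#' Positions get Gaussian jitter, accuracies are log-normal draws, and
#' artifacts are injected at the configured rates: exact duplicate rows,
#' (0, 0) fixes, and accuracy outliers (accuracy multiplied by
#' `outlier_factor`).
#'
#' @param profile a [gps_profile()].
#' @param days integer vector of study days to simulate (day 1 starts at
#'   `start_ms`).
#' @param seed integer seed.
#' @param start_ms UNIX ms of local midnight starting day 1; default
#'   2020-04-15 00:00 UTC.
#' @return data.frame `timestamp`, `latitude`, `longitude`, `accuracy`,
#'   with attributes `planted` (the noiseless path), `n_duplicates`,
#'   `n_zeros`, `n_outliers`.
#' @export
simulate_gps_trace <- function(profile, days = 1:30, seed = 1L,
                               start_ms = 1586908800000) {
  stopifnot(inherits(profile, "gps_profile"))
  deg_per_m_lat <- 1 / 111194.93   # spherical, r = 6371.0088 km
  with_seed(seed, {
    all_days <- lapply(days, function(d) {
      day0 <- start_ms + (d - 1) * 86400 * 1000
      # waypoints: (sec-of-day, lat, lon)
      wp <- data.frame(t = 0, lat = profile$home[1], lon = profile$home[2])
      sch <- profile$schedule
      if (!is.null(sch) && nrow(sch)) {
        sch_d <- sch[sch$day == d, , drop = FALSE]
        sch_d <- sch_d[order(sch_d$start_hour), , drop = FALSE]
        for (i in seq_len(nrow(sch_d))) {
          a <- profile$anchors[sch_d$anchor[i], ]
          dist_km <- haversine_km(profile$home[1], profile$home[2],
                                  a$latitude, a$longitude)
          tt <- dist_km / profile$speed_kmh * 3600
          dep <- sch_d$start_hour[i] * 3600
          ret <- sch_d$end_hour[i] * 3600
          wp <- rbind(wp,
                      data.frame(t = dep, lat = profile$home[1],
                                 lon = profile$home[2]),
                      data.frame(t = dep + tt, lat = a$latitude,
                                 lon = a$longitude),
                      data.frame(t = ret, lat = a$latitude,
                                 lon = a$longitude),
                      data.frame(t = min(ret + tt, 86399),
                                 lat = profile$home[1],
                                 lon = profile$home[2]))
        }
      }
      wp <- rbind(wp, data.frame(t = 86400, lat = profile$home[1],
                                 lon = profile$home[2]))
      wp <- wp[order(wp$t), , drop = FALSE]
      tt <- seq(0, 86399, by = profile$interval_s)
      tt <- tt + stats::runif(length(tt), -5, 5)
      tt <- pmin(pmax(tt, 0), 86399)
      tt <- sort(tt)
      lat <- stats::approx(wp$t, wp$lat, xout = tt, rule = 2)$y
      lon <- stats::approx(wp$t, wp$lon, xout = tt, rule = 2)$y
      data.frame(timestamp = day0 + round(tt * 1000), latitude = lat,
                 longitude = lon)
    })
    path <- do.call(rbind, all_days)
    planted <- path
    n <- nrow(path)
    if (profile$jitter_sd_m > 0) {
      lat0 <- mean(path$latitude)
      path$latitude <- path$latitude +
        stats::rnorm(n, sd = profile$jitter_sd_m * deg_per_m_lat)
      path$longitude <- path$longitude +
        stats::rnorm(n, sd = profile$jitter_sd_m * deg_per_m_lat /
                       cos(lat0 * pi / 180))
    }
    path$accuracy <- stats::rlnorm(n, profile$accuracy_meanlog,
                                   profile$accuracy_sdlog)
    n_out <- 0L
    if (profile$outlier_rate > 0) {
      out <- stats::runif(n) < profile$outlier_rate
      path$accuracy[out] <- path$accuracy[out] * profile$outlier_factor
      n_out <- sum(out)
    }
    n_zero <- 0L
    if (profile$zero_rate > 0) {
      z <- stats::runif(n) < profile$zero_rate
      path$latitude[z] <- 0
      path$longitude[z] <- 0
      n_zero <- sum(z)
    }
    n_dup <- 0L
    if (profile$dup_rate > 0) {
      dup_idx <- which(stats::runif(n) < profile$dup_rate)
      n_dup <- length(dup_idx)
      if (n_dup) {
        path <- rbind(path, path[dup_idx, , drop = FALSE])
        path <- path[order(path$timestamp), , drop = FALSE]
      }
    }
    rownames(path) <- NULL
    attr(path, "planted") <- planted
    attr(path, "n_duplicates") <- n_dup
    attr(path, "n_zeros") <- n_zero
    attr(path, "n_outliers") <- n_out
    path
  })
}
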