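# GPS stream preprocessing: timezone-aware localization, artifact removal
# (duplicates, accuracy outliers, (0,0) fixes), and speed-based labeling of
# stationary vs transition states.

#' Attach local civil time to sensor samples
#'
#' Converts UNIX-millisecond timestamps to local civil time using the most
#' recent timezone record at or before each sample. Samples recorded before
#' the first timezone record fall back to the first record, with a warning.
#'
#' @param samples data.frame with a `timestamp` column (UNIX ms), e.g. GPS
#'   fixes or screen events.
#' @param tz_records data.frame with columns `timestamp` (UNIX ms) and
#'   `timezone` (IANA zone name), time-sorted per participant.
#' @return `samples` with added columns `tz` (zone applied), `local_date`
#'   (class `Date`, local calendar date), `local_sec` (seconds since local
#'   midnight) and `local_datetime` (ISO-8601 local string).
#' @examples
#' localize(data.frame(timestamp = 0),
#'          data.frame(timestamp = 0, timezone = "UTC"))
#' @export
localize <- function(samples, tz_records) {
  stopifnot(nrow(tz_records) >= 1, "timezone" %in% names(tz_records))
  tz_records <- tz_records[order(tz_records$timestamp), , drop = FALSE]
  if (nrow(samples) == 0) {
    samples$tz <- character(0)
    samples$local_date <- as.Date(character(0))
    samples$local_sec <- numeric(0)
    samples$local_datetime <- character(0)
    return(samples)
  }
  idx <- findInterval(samples$timestamp, tz_records$timestamp)
  if (any(idx == 0)) {
    warning(sum(idx == 0), " sample(s) precede the first timezone record; ",
            "using the first record")
    idx[idx == 0] <- 1L
  }
  zone <- tz_records$timezone[idx]
  samples$tz <- zone
  samples$local_date <- as.Date(rep(NA_integer_, nrow(samples)),
                                origin = "1970-01-01")
  samples$local_sec <- NA_real_
  samples$local_datetime <- NA_character_
  for (z in unique(zone)) {
    sel <- zone == z
    t <- as.POSIXct(samples$timestamp[sel] / 1000, origin = "1970-01-01",
                    tz = z)
    lt <- as.POSIXlt(t, tz = z)
    samples$local_date[sel] <- as.Date(format(t, tz = z, "%Y-%m-%d"))
    samples$local_sec[sel] <- lt$hour * 3600 + lt$min * 60 + lt$sec
    samples$local_datetime[sel] <- format(t, tz = z, "%Y-%m-%dT%H:%M:%S")
  }
  samples
}

#' Pooled accuracy threshold for GPS cleaning
#'
#' The cleaning rule removes fixes whose reported accuracy exceeds the 80th
#' percentile of *all participants'* accuracies, so the threshold is
#' computed once over the pooled dataset (linear-interpolation, type-7
#' percentile) and passed to [clean_trace()].
#'
#' @param accuracies numeric vector of accuracy values (m) pooled over every
#'   participant in the dataset.
#' @param percentile percentile in (0, 100]; default 80.
#' @return The threshold in meters.
#' @export
accuracy_threshold <- function(accuracies, percentile = 80) {
  stats::quantile(accuracies, percentile / 100, na.rm = TRUE, names = FALSE,
                  type = 7)
}

#' Clean a raw GPS trace
#'
#' Removes, in order: exact duplicates (same timestamp, latitude and
#' longitude), fixes at exactly (0, 0) (a known sensing artifact), and fixes
#' with accuracy strictly greater than the pooled accuracy threshold.
#' Sorting by timestamp is applied first if needed. Idempotent.
#'
#' @param samples data.frame with `timestamp`, `latitude`, `longitude`,
#'   `accuracy` columns.
#' @param accuracy_cut accuracy threshold in meters, normally
#'   [accuracy_threshold()] over the pooled dataset; `Inf` disables the
#'   accuracy filter.
#' @return The surviving samples, with a `ledger` attribute: a named integer
#'   vector counting removals by reason (`duplicate`, `zero_coord`,
#'   `accuracy`).
#' @export
clean_trace <- function(samples, accuracy_cut = Inf) {
  ledger <- c(duplicate = 0L, zero_coord = 0L, accuracy = 0L)
  if (nrow(samples) == 0) {
    attr(samples, "ledger") <- ledger
    return(samples)
  }
  samples <- samples[order(samples$timestamp), , drop = FALSE]
  dup <- duplicated(samples[c("timestamp", "latitude", "longitude")])
  ledger["duplicate"] <- sum(dup)
  samples <- samples[!dup, , drop = FALSE]
  zero <- samples$latitude == 0 & samples$longitude == 0
  ledger["zero_coord"] <- sum(zero)
  samples <- samples[!zero, , drop = FALSE]
  bad_acc <- !is.na(samples$accuracy) & samples$accuracy > accuracy_cut
  ledger["accuracy"] <- sum(bad_acc)
  samples <- samples[!bad_acc, , drop = FALSE]
  rownames(samples) <- NULL
  attr(samples, "ledger") <- ledger
  samples
}

#' Label GPS samples as stationary or in transition
#'
#' Speed at each sample is the time derivative of position: the haversine
#' distance from the previous fix divided by elapsed time, in km/h (the
#' first sample of the trace inherits the following interval's speed).
#' Speeds strictly above 1 km/h mark a transition state; at or below,
#' stationary. Gaps longer than `gap_min` minutes split the trace into
#' segments: no dwell is credited across a gap and downstream distance sums
#' stay within segments, but the speed derivative itself is still taken
#' over the gap interval. Dwell credited to each stationary sample is the
#' time to the next sample within the segment, capped at `gap_min` (the
#' last sample of a segment gets zero dwell).
#'
#' @param trace cleaned, localized GPS data.frame (see [clean_trace()],
#'   [localize()]).
#' @param speed_threshold_kmh transition threshold; default 1 km/h.
#' @param gap_min segment-splitting gap in minutes; default 15.
#' @return The trace with added `speed_kmh`, `state` (`"stationary"` /
#'   `"transition"`), `segment` (integer id) and `dwell_sec` columns.
#'   Samples repeating a timestamp at a different position are dropped and
#'   counted in a `dropped_zero_dt` attribute.
#' @export
label_states <- function(trace, speed_threshold_kmh = 1, gap_min = 15) {
  n0 <- nrow(trace)
  if (n0 == 0) {
    trace$speed_kmh <- numeric(0)
    trace$state <- character(0)
    trace$segment <- integer(0)
    trace$dwell_sec <- numeric(0)
    return(trace)
  }
  trace <- trace[order(trace$timestamp), , drop = FALSE]
  # zero elapsed time between distinct positions has no defined derivative
  dt0 <- c(Inf, diff(trace$timestamp))
  same_pos <- c(TRUE, diff(trace$latitude) == 0 & diff(trace$longitude) == 0)
  drop <- dt0 == 0 & !same_pos
  trace <- trace[!drop, , drop = FALSE]
  n <- nrow(trace)
  gap_ms <- gap_min * 60 * 1000
  dt <- diff(trace$timestamp)              # ms, length n-1
  if (n == 1) {
    trace$speed_kmh <- 0
    trace$state <- "stationary"
    trace$segment <- 1L
    trace$dwell_sec <- 0
  } else {
    d_km <- haversine_km(trace$latitude[-n], trace$longitude[-n],
                         trace$latitude[-1], trace$longitude[-1])
    sp <- ifelse(dt > 0, d_km / (dt / 3.6e6), 0)   # km/h over interval i..i+1
    segment <- cumsum(c(1L, as.integer(dt > gap_ms)))
    # speed at sample i is the time derivative over the preceding interval,
    # gaps included (a gap suppresses dwell and distance credit, not the
    # derivative); the very first sample inherits the following interval's
    speed <- c(sp[1], sp)
    dwell <- c(pmin(dt, gap_ms) / 1000, 0)
    dwell[c(dt > gap_ms, FALSE)] <- 0        # no dwell across a gap
    trace$speed_kmh <- speed
    trace$state <- ifelse(speed > speed_threshold_kmh, "transition",
                          "stationary")
    trace$segment <- segment
    trace$dwell_sec <- ifelse(trace$state == "stationary", dwell, 0)
  }
  rownames(trace) <- NULL
  attr(trace, "dropped_zero_dt") <- sum(drop)
  trace
}
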