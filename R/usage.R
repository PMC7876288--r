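# Phone usage features from screen event streams: a session spans unlock ->
# lock; frequency counts unlock events; duration sums session minutes.

#' Segment screen events into usage sessions
#'
#' A state machine over the time-sorted event stream: each `unlocked` event
#' opens a session, closed by the next `locked` event. A second unlock
#' without an intervening lock closes the prior session at the new unlock
#' (the lock event was evidently lost). An unmatched trailing unlock is
#' closed at the last event in the stream. Sessions longer than
#' `max_session_h` hours are truncated to that length and counted in the
#' `truncated` attribute; locks with no open session are ignored and counted
#' in `orphan_locks`. Sessions crossing local midnight are split at midnight
#' so daily attribution is exact.
#'
#' @param events localized data.frame (see [localize()]) with columns
#'   `timestamp` (UNIX ms), `status` (`"on"`, `"off"`, `"locked"`,
#'   `"unlocked"`), `local_date`, `local_sec`.
#' @param max_session_h session cap in hours; default 12.
#' @return data.frame of sessions: `start_ms`, `end_ms`, `local_date`,
#'   `duration_min`, `unlock` (TRUE for the row carrying the opening unlock
#'   event, FALSE for continuation rows created by a midnight split).
#' @export
sessionize <- function(events, max_session_h = 12) {
  stopifnot(all(events$status %in% c("on", "off", "locked", "unlocked")))
  events <- events[order(events$timestamp), , drop = FALSE]
  n <- nrow(events)
  open_ms <- NA_real_
  raw <- list()
  truncated <- 0L
  orphan_locks <- 0L
  close_at <- function(start, end) {
    cap <- max_session_h * 3600 * 1000
    if (end - start > cap) {
      truncated <<- truncated + 1L
      end <- start + cap
    }
    if (end > start) raw[[length(raw) + 1L]] <<- c(start, end)
  }
  for (i in seq_len(n)) {
    st <- events$status[i]
    ts <- events$timestamp[i]
    if (st == "unlocked") {
      if (!is.na(open_ms)) close_at(open_ms, ts)
      open_ms <- ts
    } else if (st == "locked") {
      if (!is.na(open_ms)) {
        close_at(open_ms, ts)
        open_ms <- NA_real_
      } else {
        orphan_locks <- orphan_locks + 1L
      }
    }
  }
  if (!is.na(open_ms) && n > 0) close_at(open_ms, events$timestamp[n])

  out <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                    local_date = as.Date(character(0)),
                    duration_min = numeric(0), unlock = logical(0))
  if (length(raw)) {
    # local-midnight offsets: local_sec gives seconds since local midnight
    # at each event, so midnight (ms since epoch) = timestamp - local_sec*1000
    loc <- function(ms) {
      i <- findInterval(ms, events$timestamp)
      i[i == 0] <- 1L
      date <- events$local_date[i]
      mid_ms <- events$timestamp[i] - events$local_sec[i] * 1000
      # roll forward across whole local days if ms lies past this day's end
      # (fixed 24 h days; DST shifts at most misattribute one hour per switch)
      adv <- floor((ms - mid_ms) / (86400 * 1000))
      if (adv > 0) {
        date <- date + adv
        mid_ms <- mid_ms + adv * 86400 * 1000
      }
      list(date = date, mid_ms = mid_ms)
    }
    rows <- list()
    for (s in raw) {
      start <- s[1]; end <- s[2]
      first <- TRUE
      repeat {
        a <- loc(start)
        day_end <- a$mid_ms + 86400 * 1000
        piece_end <- min(end, day_end)
        rows[[length(rows) + 1L]] <- data.frame(
          start_ms = start, end_ms = piece_end, local_date = a$date,
          duration_min = (piece_end - start) / 60000, unlock = first)
        first <- FALSE
        if (piece_end >= end) break
        start <- piece_end
      }
    }
    out <- do.call(rbind, rows)
  }
  attr(out, "truncated") <- truncated
  attr(out, "orphan_locks") <- orphan_locks
  out
}

#' Daily phone-usage features
#'
#' Usage frequency is the raw count of unlock events on the local date;
#' usage duration sums the session minutes attributed to that date by
#' [sessionize()] (midnight-split pieces count toward the day they fall in).
#'
#' @param sessions output of [sessionize()].
#' @param events the localized event stream the sessions came from.
#' @param day a `Date` (local calendar date).
#' @return A list with `usage_frequency` (count) and `usage_duration`
#'   (minutes); both 0 when the day has no events, with `covered = FALSE`.
#' @export
daily_usage_features <- function(sessions, events, day) {
  freq <- sum(events$status == "unlocked" & events$local_date == day)
  dur <- if (nrow(sessions)) {
    sum(sessions$duration_min[sessions$local_date == day])
  } else 0
  covered <- any(events$local_date == day)
  list(usage_frequency = as.integer(freq), usage_duration = dur,
       covered = covered)
}
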