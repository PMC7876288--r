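# Screen sessionization and daily usage features.

screen_events <- function(times_min, statuses, day0_ms = 0) {
  ev <- data.frame(timestamp = day0_ms + times_min * 60000,
                   status = statuses)
  localize(ev, utc_records())
}

test_that("an unlock-lock pair forms one session of the right length", {
  ev <- screen_events(c(600, 605), c("unlocked", "locked"))
  s <- sessionize(ev)
  expect_equal(nrow(s), 1)
  expect_equal(s$duration_min, 5)
})

test_that("a lost lock closes the prior session at the next unlock", {
  ev <- screen_events(c(600, 610, 612),
                      c("unlocked", "unlocked", "locked"))
  s <- sessionize(ev)
  expect_equal(s$duration_min, c(10, 2))
})

test_that("sessions crossing midnight split for daily attribution", {
  # unlock 23:50, lock 00:10 next day
  ev <- screen_events(c(23 * 60 + 50, 24 * 60 + 10),
                      c("unlocked", "locked"))
  s <- sessionize(ev)
  expect_equal(nrow(s), 2)
  expect_equal(s$duration_min, c(10, 10))
  expect_equal(as.integer(diff(s$local_date)), 1L)
  d0 <- as.Date("1970-01-01")
  f0 <- daily_usage_features(s, ev, d0)
  f1 <- daily_usage_features(s, ev, d0 + 1)
  expect_equal(f0$usage_frequency, 1L)
  expect_equal(f1$usage_frequency, 0L)
  expect_equal(f0$usage_duration, 10)
  expect_equal(f1$usage_duration, 10)
})

test_that("orphan locks, trailing unlocks and the session cap are handled", {
  ev <- screen_events(c(10, 600), c("locked", "unlocked"))
  s <- sessionize(ev)
  expect_equal(attr(s, "orphan_locks"), 1L)
  expect_equal(nrow(s), 0)  # trailing unlock closes at the last event = itself

  # unlock open for 20 h closed by a final lock: truncated at 12 h
  ev <- screen_events(c(0, 20 * 60), c("unlocked", "locked"))
  s <- sessionize(ev)
  expect_equal(attr(s, "truncated"), 1L)
  expect_equal(sum(s$duration_min), 12 * 60)
})

test_that("daily durations conserve total session time under splitting", {
  set.seed(21)
  # random sessions over 5 days, some crossing midnight
  starts <- sort(runif(40, 0, 5 * 1440 - 30))
  durs <- runif(40, 1, 120)
  ev <- list()
  t_prev <- 0
  for (i in seq_along(starts)) {
    st <- max(starts[i], t_prev + 1)
    en <- st + durs[i]
    ev[[i]] <- data.frame(times = c(st, en),
                          status = c("unlocked", "locked"))
    t_prev <- en
  }
  ev <- do.call(rbind, ev)
  evl <- screen_events(ev$times, ev$status)
  s <- sessionize(evl)
  total_in <- sum(pmin(diff(matrix(ev$times, nrow = 2))[1, ], Inf))
  by_day <- tapply(s$duration_min, s$local_date, sum)
  expect_equal(sum(by_day), sum(s$duration_min))
  expect_equal(sum(s$duration_min),
               sum(vapply(seq(0, 9), function(d) {
                 daily_usage_features(s, evl,
                                      as.Date("1970-01-01") + d)$usage_duration
               }, 0)), tolerance = 1 / 60)

  # frequency equals the raw unlock count regardless of pairing quirks
  expect_equal(sum(vapply(seq(0, 9), function(d) {
    daily_usage_features(s, evl, as.Date("1970-01-01") + d)$usage_frequency
  }, 0)), sum(evl$status == "unlocked"))
})

test_that("a day without events reports zero with a coverage flag", {
  ev <- screen_events(c(600, 605), c("unlocked", "locked"))
  s <- sessionize(ev)
  f <- daily_usage_features(s, ev, as.Date("1970-01-05"))
  expect_equal(f$usage_frequency, 0L)
  expect_equal(f$usage_duration, 0)
  expect_false(f$covered)
})
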