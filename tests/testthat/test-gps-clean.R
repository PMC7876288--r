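test_that("localization resolves IANA zones and zone switches", {
  # epoch identity in UTC
  out <- localize(data.frame(timestamp = 0), utc_records())
  expect_equal(out$local_datetime, "1970-01-01T00:00:00")
  # Helsinki was UTC+2 at the epoch
  out <- localize(data.frame(timestamp = 0),
                  data.frame(timestamp = 0, timezone = "Europe/Helsinki"))
  expect_equal(out$local_datetime, "1970-01-01T02:00:00")
  expect_equal(out$local_sec, 2 * 3600)

  # mid-study switch UTC -> UTC+3: a piecewise lookup computed by hand
  tzr <- data.frame(timestamp = c(0, 1e7), timezone = c("UTC", "Etc/GMT-3"))
  s <- localize(data.frame(timestamp = c(5e6, 2e7)), tzr)
  expect_equal(s$local_sec[1], 5e3 %% 86400)
  expect_equal(s$local_sec[2], (2e4 + 3 * 3600) %% 86400)

  # sample before the first record falls back with a warning
  expect_warning(
    out <- localize(data.frame(timestamp = -1000),
                    data.frame(timestamp = 0, timezone = "UTC")),
    "precede")
  expect_equal(out$tz, "UTC")
})

test_that("cleaning removes duplicates, zero coordinates and accuracy outliers", {
  base <- gps_df((1:10) * 1000, 60 + (1:10) * 1e-5, 24.9, accuracy = 5)
  withdup <- rbind(base, base[c(2, 5, 9), ])
  out <- clean_trace(withdup)
  expect_equal(nrow(out), 10)
  expect_equal(attr(out, "ledger")[["duplicate"]], 3L)

  z <- rbind(base, gps_df(99000, 0, 0))
  out <- clean_trace(z)
  expect_equal(attr(out, "ledger")[["zero_coord"]], 1L)
  expect_false(any(out$latitude == 0 & out$longitude == 0))

  # survivors of the percentile filter match an independent brute-force
  # filter using a separately computed type-7 percentile
  set.seed(11)
  acc <- sample(1:100)
  tr <- gps_df((1:100) * 1000, 60 + (1:100) * 1e-5, 24.9, accuracy = acc)
  cut <- accuracy_threshold(acc, 80)
  expect_equal(cut, unname(quantile(acc, 0.8)))   # oracle: stats quantile
  out <- clean_trace(tr, cut)
  brute <- tr[!(tr$accuracy > cut), ]
  expect_equal(out$timestamp, brute$timestamp)
  expect_equal(attr(out, "ledger")[["accuracy"]], sum(acc > cut))
})

test_that("cleaning is idempotent and handles empty input", {
  e <- clean_trace(gps_df(numeric(0), numeric(0), numeric(0), numeric(0)))
  expect_equal(nrow(e), 0)
  expect_equal(sum(attr(e, "ledger")), 0L)

  tr <- rbind(gps_df(1:6 * 1000, 60, 24.9, accuracy = c(1, 2, 3, 99, 5, 6)),
              gps_df(2000, 60, 24.9, accuracy = 2),
              gps_df(7000, 0, 0))
  once <- clean_trace(tr, 50)
  twice <- clean_trace(once, 50)
  attr(once, "ledger") <- NULL
  attr(twice, "ledger") <- NULL
  expect_equal(twice, once)
})

test_that("speed labeling applies the strict 1 km/h rule with gap splitting", {
  # two samples 1 km apart, 30 min apart -> 2 km/h -> transition
  tr <- prep_trace(gps_df(c(0, 30 * 60 * 1000), c(60, north_of(60, 1)), 24.9))
  expect_equal(tr$speed_kmh[2], 2, tolerance = 1e-3)
  expect_equal(tr$state[2], "transition")

  # identical consecutive positions -> stationary at speed 0
  tr <- prep_trace(gps_df(c(0, 60000), 60, 24.9))
  expect_equal(tr$speed_kmh, c(0, 0))
  expect_equal(tr$state, c("stationary", "stationary"))

  # boundary probes either side of 1 km/h over one hour (the threshold is
  # a strict inequality, so just-below stays stationary)
  for (case in list(c(0.99, "stationary"), c(0.9999, "stationary"),
                    c(1.01, "transition"))) {
    d <- as.numeric(case[1])
    tr <- prep_trace(gps_df(c(0, 3.6e6), c(60, north_of(60, d)), 24.9))
    expect_equal(tr$state[2], case[2])
  }

  # a 20-minute hole splits segments and credits no dwell across it
  tr <- prep_trace(gps_df(c(0, 60, 1260, 1320) * 1000, 60, 24.9))
  expect_equal(tr$segment, c(1L, 1L, 2L, 2L))
  expect_equal(tr$dwell_sec, c(60, 0, 60, 0))

  # first sample of a segment inherits the following interval's speed
  tr <- prep_trace(gps_df(c(0, 3.6e6), c(60, north_of(60, 5)), 24.9))
  expect_equal(tr$speed_kmh[1], tr$speed_kmh[2])

  # zero elapsed time between distinct positions is dropped and counted
  tr <- prep_trace(gps_df(c(0, 0, 60000), c(60, 60.1, 60), c(24.9, 24.9, 24.9)))
  expect_equal(attr(tr, "dropped_zero_dt"), 1L)
  expect_equal(nrow(tr), 2)
})
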