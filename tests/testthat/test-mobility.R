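# Feature extraction over labeled traces: closed-form entropy values,
# distance and homestay behaviour, and the undefined-feature conventions.

two_cluster_trace <- function(share1 = 0.5, total_hours = 10) {
  anchors <- data.frame(latitude = c(60, north_of(60, 3)),
                        longitude = 24.9)
  dwell <- c(share1, 1 - share1) * total_hours * 3600
  tr <- anchor_trace(anchors, dwell)
  tr <- prep_trace(tr)
  tr$state <- "stationary"          # drop the single travel hop label
  tr$dwell_sec <- 60                # uniform credit per sample
  tr
}

test_that("equal dwell in two clusters gives entropy ln 2, normalized 1", {
  tr <- two_cluster_trace(0.5)
  cl <- cluster_stationary(tr, seed = 1)
  f <- extract_mobility_features(tr, cl)
  expect_equal(f$entropy, log(2), tolerance = 1e-9)
  expect_equal(f$normalized_entropy, 1, tolerance = 1e-9)
})

test_that("a single cluster gives entropy 0 and normalized entropy 0", {
  tr <- two_cluster_trace(1)
  cl <- cluster_stationary(tr, seed = 1)
  expect_equal(cl$k, 1L)
  f <- extract_mobility_features(tr, cl)
  expect_equal(f$entropy, 0)
  expect_equal(f$normalized_entropy, 0)
})

test_that("dwell shares (0.7, 0.3) give 0.6109 nats", {
  tr <- two_cluster_trace(0.7)
  cl <- cluster_stationary(tr, seed = 1)
  f <- extract_mobility_features(tr, cl)
  expect_equal(f$entropy, -(0.7 * log(0.7) + 0.3 * log(0.3)),
               tolerance = 1e-9)
  expect_equal(round(f$entropy, 4), 0.6109)
})

test_that("entropy is maximal and normalization N-invariant at uniform dwell", {
  for (N in 2:5) {
    h <- location_entropy(rep(1, N))
    expect_equal(h$entropy, log(N), tolerance = 1e-12)
    expect_equal(h$normalized_entropy, 1, tolerance = 1e-12)
  }
  # non-uniform shares are strictly below the maximum
  set.seed(1)
  for (i in 1:20) {
    p <- rgamma(4, 1)
    p <- p / sum(p)
    if (max(p) - min(p) > 1e-3) {
      expect_lt(location_entropy(p)$entropy, log(4))
    }
  }
})

test_that("merging two clusters never increases entropy", {
  set.seed(7)
  for (i in 1:50) {
    dwell <- rgamma(5, 1)
    merged <- c(dwell[1] + dwell[2], dwell[-(1:2)])
    expect_lte(location_entropy(merged)$entropy,
               location_entropy(dwell)$entropy + 1e-12)
  }
})

test_that("total distance is collinear-midpoint invariant and non-negative", {
  a <- gps_df(c(0, 6e5), c(60, north_of(60, 4)), 24.9)
  b <- gps_df(c(0, 3e5, 6e5), c(60, north_of(60, 2), north_of(60, 4)),
              24.9)
  fa <- extract_mobility_features(prep_trace(a),
                                  list(k = 0L, assignment = NULL))
  fb <- extract_mobility_features(prep_trace(b),
                                  list(k = 0L, assignment = NULL))
  expect_equal(fa$total_distance, fb$total_distance, tolerance = 1e-9)
  expect_gte(fa$total_distance, 0)
  expect_equal(fa$total_distance, 4, tolerance = 1e-5)
})

test_that("undefined sub-features carry reasons without poisoning others", {
  # two samples only: variance undefined, distance still computed
  tr <- prep_trace(gps_df(c(0, 60000), 60, 24.9))
  cl <- cluster_stationary(tr, seed = 1)
  f <- extract_mobility_features(tr, cl)
  expect_true(is.na(f$location_variance))
  expect_equal(attr(f, "reasons")$location_variance, "too_few_stationary")
  expect_false(is.na(f$entropy))

  # no night-time samples: homestay undefined, entropy fine
  tr <- two_cluster_trace(0.5)
  tr$local_sec <- 12 * 3600
  cl <- cluster_stationary(tr, seed = 1)
  f <- extract_mobility_features(tr, cl)
  expect_true(is.na(f$homestay))
  expect_equal(attr(f, "reasons")$homestay, "no_night_samples")
  expect_equal(f$normalized_entropy, 1, tolerance = 1e-9)
})

test_that("homestay divides home-cluster dwell by 24 h per window day", {
  # 6 h dwell at home (night-heavy) + 18 h elsewhere, one-day window
  anchors <- data.frame(latitude = c(60, north_of(60, 3)), longitude = 24.9)
  tr <- anchor_trace(anchors, c(6, 18) * 3600)
  tr <- prep_trace(tr)
  tr$state <- "stationary"
  tr$dwell_sec <- 60
  cl <- cluster_stationary(tr, seed = 1)
  f <- extract_mobility_features(tr, cl, window = 1)
  # home = cluster holding the 00:00-06:00 fixes = the first anchor
  expect_equal(f$homestay, 6 / 24, tolerance = 0.01)
  expect_equal(attr(f, "home_cluster"),
               cl$assignment[1])
})
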