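# The synthetic cohort generators: artifact injection, planted-effect
# structure, MAR construction, determinism.

test_that("a home-only noiseless profile stays within 1 m of home", {
  prof <- gps_profile(home = c(60.2, 24.9), jitter_sd_m = 0)
  tr <- simulate_gps_trace(prof, days = 1:2, seed = 4)
  tr <- localize(tr, utc_records())
  tr <- clean_trace(tr)
  d_m <- haversine_km(tr$latitude, tr$longitude, 60.2, 24.9) * 1000
  expect_lt(max(d_m), 1)
  tr$study_day <- 1L
  lab <- label_states(tr)
  expect_equal(mean(lab$state == "stationary"), 1)
})

test_that("injected artifact counts equal a brute-force recount", {
  prof_dup <- gps_profile(home = c(60.2, 24.9), dup_rate = 0.05)
  tr <- simulate_gps_trace(prof_dup, days = 1, seed = 8)
  expect_gt(attr(tr, "n_duplicates"), 10)   # ~72 expected on 1440 samples
  expect_equal(sum(duplicated(tr[c("timestamp", "latitude", "longitude")])),
               attr(tr, "n_duplicates"))

  prof_zero <- gps_profile(home = c(60.2, 24.9), zero_rate = 0.02)
  tr <- simulate_gps_trace(prof_zero, days = 1, seed = 8)
  expect_equal(sum(tr$latitude == 0 & tr$longitude == 0),
               attr(tr, "n_zeros"))

  prof_out <- gps_profile(home = c(60.2, 24.9), outlier_rate = 0.03,
                          outlier_factor = 1000)
  tr <- simulate_gps_trace(prof_out, days = 1, seed = 8)
  expect_equal(sum(tr$accuracy > 500), attr(tr, "n_outliers"))
})

test_that("a planted 2 km round trip yields ~4 km of extracted distance", {
  prof <- gps_profile(home = c(60.2, 24.9),
                      anchors = data.frame(latitude = north_of(60.2, 2),
                                           longitude = 24.9),
                      schedule = data.frame(day = 1, anchor = 1,
                                            start_hour = 10, end_hour = 13),
                      speed_kmh = 5, jitter_sd_m = 0)
  tr <- simulate_gps_trace(prof, days = 1, seed = 2)
  lab <- prep_trace(tr)
  f <- extract_mobility_features(lab, list(k = 0L, assignment = NULL))
  expect_lt(abs(f$total_distance - 4) / 4, 0.05)
})

test_that("overlapping schedule entries are rejected", {
  expect_error(
    gps_profile(home = c(60, 24),
                anchors = data.frame(latitude = 60.1, longitude = 24),
                schedule = data.frame(day = c(1, 1), anchor = 1,
                                      start_hour = c(9, 10),
                                      end_hour = c(11, 12))),
    "overlapping")
})

test_that("masking rates hit their targets and are MAR by construction", {
  cfg <- cohort_config(n_participants = 500, seed = 19)
  sim <- simulate_model_table(cfg, n_windows = 2)
  frac_dass <- mean(is.na(sim$table$depression))
  expect_lt(abs(frac_dass - 0.10), 0.03)
  frac_sens <- mean(is.na(sim$table$tst))
  expect_lt(abs(frac_sens - 0.091), 0.03)
  # the driver covariate is never masked, and a logistic fit of the
  # missingness indicator on it recovers a clearly positive coefficient
  expect_false(anyNA(sim$table$usage_frequency))
  g <- glm(is.na(sim$table$depression) ~ sim$table$usage_frequency,
           family = binomial)
  z <- coef(summary(g))[2, ]
  expect_gt(z["Estimate"], 0.5)
  expect_lt(z["Pr(>|z|)"], 1e-4)
})

test_that("null planted effects produce near-zero pooled slope estimates", {
  ests <- vapply(1:100, function(r) {
    cfg <- cohort_config(n_participants = 500, dass_missing_rate = 0,
                         sensing_missing_rate = 0, seed = 900 + r)
    sim <- simulate_model_table(cfg, n_windows = 2, features = "homestay")
    f <- fit_mlm(sim$table, "anxiety", "homestay",
                 random_slopes = character(0), df_method = "residual")
    coef(f)[["homestay"]]
  }, 0)
  expect_lt(abs(mean(ests)), 0.02)
})

test_that("generation is byte-identical under the same seed", {
  cfg <- cohort_config(n_participants = 3, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$gps, b$gps)
  expect_identical(a$dass, b$dass)
  expect_identical(a$wearable, b$wearable)
  s1 <- simulate_model_table(cfg)
  s2 <- simulate_model_table(cfg)
  expect_identical(s1, s2)
})

test_that("DASS item responses sum to the planted (clipped) subscores", {
  cfg <- cohort_config(n_participants = 6, dass_missing_rate = 0,
                       sensing_missing_rate = 0,
                       planted_betas = list(depression = c(valence = -0.39)),
                       seed = 55)
  ch <- simulate_cohort(cfg)
  scored <- score_dass_table(ch$dass)
  lat <- ch$truth$latent_windows
  for (i in which(scored$assessment_point %in% c("T1", "T2"))) {
    w <- match(scored$assessment_point[i], c("T1", "T2"))
    y <- lat$depression[lat$participant == scored$participant[i] &
                          lat$window == w]
    want <- min(max(round(3.78 + 3.48 * y), 0), 21)
    expect_equal(scored$depression[i], want)
  }
  # item ratings stay on the 0-3 grid
  items <- as.matrix(ch$dass[paste0("item_", 1:21)])
  expect_true(all(items %in% 0:3))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_participants = 1), "n_participants")
  expect_error(cohort_config(dass_missing_rate = 1.2))
  expect_error(cohort_config(planted_betas = list(depression = c(bogus = 1))),
               "unrecognized feature")
})
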