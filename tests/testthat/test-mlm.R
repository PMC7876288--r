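# Mixed-model fitting: noiseless limits, degenerate-variance behaviour,
# and calibration of the slope test.

test_that("with zero between-person variance the fit matches OLS", {
  set.seed(12)
  n <- 300
  tb <- data.frame(participant = rep(sprintf("p%03d", 1:100), 3),
                   valence = rnorm(n))
  # center the predictor within participants so the GLS and OLS estimators
  # coincide exactly whatever the (boundary) variance estimate
  tb$valence <- tb$valence - ave(tb$valence, tb$participant)
  tb$depression <- 0.4 * tb$valence + rnorm(n)   # no person effect
  f <- fit_mlm(tb, "depression", "valence", random_slopes = character(0))
  ols <- lm(depression ~ valence, tb)
  expect_equal(coef(f)[["valence"]], coef(ols)[["valence"]],
               tolerance = 1e-4)
  expect_equal(coef(f)[["(Intercept)"]], coef(ols)[["(Intercept)"]],
               tolerance = 1e-4)
})

test_that("a noiseless linear relation is recovered to optimizer tolerance", {
  tb <- data.frame(participant = rep(sprintf("p%02d", 1:30), each = 4),
                   valence = rnorm(120))
  tb$depression <- 0.25 * tb$valence          # exactly determined
  f <- fit_mlm(tb, "depression", "valence")
  expect_equal(coef(f)[["valence"]], 0.25, tolerance = 1e-6)
})

test_that("boundary random-slope fits fall back to random intercept, flagged", {
  set.seed(13)
  cfg <- cohort_config(n_participants = 60, slope_sd = 0,
                       dass_missing_rate = 0, sensing_missing_rate = 0,
                       planted_betas = list(depression = c(valence = -0.3)),
                       seed = 31)
  sim <- simulate_model_table(cfg, n_windows = 2, features = "valence")
  f <- fit_mlm(sim$table, "depression", "valence")
  # with 2 obs/person and no true slope heterogeneity the slope variance
  # almost surely hits the boundary
  expect_true(f$boundary_refit)
  expect_length(f$random_slopes, 0)
  expect_true(f$converged)
})

test_that("planted slopes are recovered and the null slope test is calibrated", {
  # recovery at a planted beta of 0.25
  ests <- vapply(1:20, function(r) {
    cfg <- cohort_config(n_participants = 100,
                         planted_betas = list(depression = c(tst = 0.25)),
                         dass_missing_rate = 0, sensing_missing_rate = 0,
                         seed = 400 + r)
    sim <- simulate_model_table(cfg, n_windows = 4, features = "tst")
    f <- fit_mlm(sim$table, "depression", "tst")
    coef(f)[["tst"]]
  }, 0)
  expect_lt(abs(mean(ests) - 0.25), 0.05)

  # type-I of the Satterthwaite slope t-test under the null
  rej <- vapply(1:120, function(r) {
    cfg <- cohort_config(n_participants = 75, dass_missing_rate = 0,
                         sensing_missing_rate = 0, seed = 700 + r)
    sim <- simulate_model_table(cfg, n_windows = 4, features = "tst")
    f <- fit_mlm(sim$table, "depression", "tst")
    f$coefficients$p[f$coefficients$term == "tst"] < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})

test_that("insufficient grouping is rejected", {
  tb <- data.frame(participant = "a", valence = rnorm(10),
                   depression = rnorm(10))
  expect_error(fit_mlm(tb, "depression", "valence"), "2 participants")
})
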