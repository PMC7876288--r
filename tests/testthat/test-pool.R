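# Rubin's rules and the pooled likelihood-ratio test.

fit_pair <- function(seed, predictors = "valence", n = 50) {
  cfg <- cohort_config(n_participants = n, dass_missing_rate = 0,
                       sensing_missing_rate = 0,
                       planted_betas = list(depression = c(valence = -0.3)),
                       seed = seed)
  sim <- simulate_model_table(cfg, n_windows = 2,
                              features = c("valence", "usage_frequency"))
  fit_mlm(sim$table, "depression", predictors)
}

test_that("pooling m identical fits reproduces single-fit inference (B = 0)", {
  f <- fit_pair(21)
  pl <- pool_rubin(list(f, f, f, f))
  expect_equal(unname(pl$B), rep(0, 2))
  expect_equal(pl$coefficients$estimate, f$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(pl$coefficients$se, f$coefficients$se, tolerance = 1e-10)
})

test_that("pooled variance matches the hand W + (1 + 1/m) B formula", {
  # two toy 'fits' with printed-by-hand numbers
  mk <- function(est, se) {
    structure(list(coefficients = data.frame(term = c("(Intercept)", "x"),
                                             estimate = est, se = se,
                                             df = c(10, 10), t = NA, p = NA),
                   outcome = "y", predictors = "x", formula = y ~ x,
                   n = 20, boundary_refit = FALSE),
              class = "mlm_fit")
  }
  pl <- pool_rubin(list(mk(c(0, 1), c(0.5, 0.2)),
                        mk(c(0.2, 1.4), c(0.5, 0.3))))
  # for x: qbar = 1.2, W = (0.04+0.09)/2 = 0.065, B = var(c(1,1.4)) = 0.08
  # T = 0.065 + 1.5*0.08 = 0.185
  expect_equal(pl$coefficients$estimate[2], 1.2)
  expect_equal(pl$coefficients$se[2]^2, 0.185, tolerance = 1e-12)
})

test_that("pooled estimates are invariant to fit order", {
  f1 <- fit_pair(22)
  f2 <- fit_pair(23)
  f3 <- fit_pair(24)
  a <- pool_rubin(list(f1, f2, f3))
  b <- pool_rubin(list(f3, f1, f2))
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-12)
})

test_that("m = 1 pooled LRT equals the classical chi-square transform", {
  f0 <- fit_pair(25, predictors = character(0))
  f1 <- fit_pair(25)
  l <- lrt_pooled(list(f0), list(f1))
  d <- 2 * (f1$logLik - f0$logLik)
  expect_equal(l$p, pchisq(d, df = 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(l$df1, 1)
})

test_that("comparing a model against itself is a null comparison", {
  tbcfg <- cohort_config(n_participants = 50, seed = 30)
  sim <- simulate_model_table(tbcfg, n_windows = 2,
                              features = c("valence", "usage_frequency"))
  imp <- impute_mpmm(sim$table[c("participant", "window", "valence",
                                 "usage_frequency", "depression")],
                     m = 3, iterations = 3, seed = 2)
  f0 <- lapply(imp$tables, function(d) fit_mlm(d, "depression",
                                               character(0)))
  f1 <- lapply(imp$tables, function(d) fit_mlm(d, "depression", "valence",
                                               random_slopes = character(0)))
  # genuinely nested comparison runs
  l <- lrt_pooled(f0, f1)
  expect_true(is.finite(l$F) && l$F >= 0)
  expect_true(l$p >= 0 && l$p <= 1)
  # non-nested or identical models are rejected by the formula check
  expect_error(lrt_pooled(f1, f1), "not nested")
  f2 <- lapply(imp$tables, function(d) fit_mlm(d, "depression",
                                               "usage_frequency"))
  expect_error(lrt_pooled(f1, f2), "not nested")
})

test_that("pooling rejects mismatched formulas and m = 0", {
  expect_error(pool_rubin(list()), "m = 0")
  f1 <- fit_pair(26)
  f0 <- fit_pair(26, predictors = character(0))
  expect_error(pool_rubin(list(f1, f0)), "same model formula")
})
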