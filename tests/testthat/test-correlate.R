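# Spearman/Holm correlation layer and the intraclass correlation.
# (holm_brute, the brute-force step-down oracle, lives in the helpers.)

test_that("Spearman rho is 1 under any strictly monotone transform", {
  set.seed(2)
  tb <- data.frame(participant = "a", window = 1,
                   valence = rnorm(30))
  tb$depression <- exp(tb$valence)
  tb$anxiety <- tb$valence^3
  r <- spearman_with_holm(tb, outcomes = c("depression", "anxiety"))
  expect_equal(r$rho, rep(1, 2), tolerance = 1e-12)
  # and -1 under a strictly decreasing transform
  tb$anxiety <- -expm1(tb$valence)
  r <- spearman_with_holm(tb, outcomes = "anxiety")
  expect_equal(r$rho, -1, tolerance = 1e-12)
})

test_that("rho and p match the rank-correlation t approximation", {
  set.seed(3)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40)
  tb <- data.frame(participant = "a", window = 1, valence = x,
                   depression = y)
  r <- spearman_with_holm(tb, outcomes = "depression")
  rho <- cor(x, y, method = "spearman")   # oracle: stats::cor
  expect_equal(r$rho, rho, tolerance = 1e-12)
  tval <- rho * sqrt(38 / (1 - rho^2))
  expect_equal(r$p_raw, 2 * pt(-abs(tval), 38), tolerance = 1e-12)
})

test_that("Holm adjustment is cluster-wise and matches brute-force step-down", {
  set.seed(4)
  # all 16 features x 3 outcomes on random data
  n <- 40
  tb <- data.frame(participant = rep(sprintf("p%02d", 1:(n / 2)), each = 2),
                   window = rep(1:2, n / 2))
  for (f in names(feature_clusters())) tb[[f]] <- rnorm(n)
  for (oc in c("depression", "anxiety", "stress")) tb[[oc]] <- rnorm(n)
  r <- spearman_with_holm(tb)
  cl <- feature_clusters()
  for (g in unique(cl)) {
    for (oc in c("depression", "anxiety", "stress")) {
      sel <- r$cluster == g & r$outcome == oc
      expect_equal(r$p_adjusted[sel], holm_brute(r$p_raw[sel]),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(r$p_adjusted >= r$p_raw - 1e-12))
  expect_true(all(r$p_adjusted <= 1))
})

test_that("Holm on many random p-vectors equals stats::p.adjust and brute force", {
  set.seed(6)
  for (i in 1:200) {
    p <- runif(sample(2:8, 1))
    expect_equal(holm_brute(p), p.adjust(p, "holm"), tolerance = 1e-14)
  }
  # worked 2-test family: (0.01, 0.04) -> (0.02, 0.04)
  expect_equal(holm_brute(c(0.01, 0.04)), c(0.02, 0.04))
})

test_that("ICC matches a hand one-way ANOVA and behaves at the extremes", {
  # hand-computed two-participant example (balanced, k0 = 2):
  y <- c(1, 2, 5, 6)
  g <- c("a", "a", "b", "b")
  # MSB = 16, MSW = 0.5, sb2 = (16 - 0.5)/2 = 7.75 -> ICC = 7.75/8.25
  expect_equal(icc(y, g), 7.75 / 8.25, tolerance = 1e-8)

  # duplicate rows per participant: no within variance -> ICC ~ 1
  y <- rep(rnorm(10, sd = 2), each = 2)
  g <- rep(1:10, each = 2)
  expect_gt(icc(y, g), 0.99)

  # outcome independent of participant: ICC near 0 at large n
  set.seed(9)
  y <- rnorm(2000)
  g <- rep(1:500, each = 4)
  expect_lt(abs(icc(y, g)), 0.05)

  # degenerate groupings are undefined
  expect_true(is.na(icc(c(1, 2), c("a", "b"))))
  expect_true(is.na(icc(c(1, 2, 3), c("a", "a", "a"))))
})
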