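# Window-level synthetic data: standardized features with planted
# standardized slopes on the outcomes, person-level random intercepts,
# optional random slopes, and missing-at-random masking driven by an
# always-observed covariate (phone-usage frequency).

#' Configuration for a synthetic cohort
#'
#' Captures the study conditions the generators emulate: cohort size, a
#' 30-day window with assessments at days 1 (T0), 16 (T1) and 31 (T2),
#' planted standardized feature-outcome slopes, and the observed
#' missingness rates (10% of assessments, 9.1% of sensing days).
#'
#' @param n_participants number of participants (>= 2).
#' @param study_days length of the sensing window; default 30.
#' @param assessment_days assessment day indices; default `c(1, 16, 31)`.
#' @param planted_betas named list keyed by outcome (`depression`,
#'   `anxiety`, `stress`), each a named numeric vector of standardized
#'   slopes over recognized feature names; omitted outcomes are null.
#' @param between_person_sd,within_person_sd SDs of the person-level and
#'   window-level feature components; defaults 0.6 / 0.8 (unit total
#'   variance).
#' @param feature_cor exchangeable correlation among features via a common
#'   person/window factor; default 0.
#' @param outcome_icc share of the outcome's residual variance at the
#'   person level; default 0.4.
#' @param slope_sd SD of person-specific deviations around each planted
#'   slope; default 0.1.
#' @param dass_missing_rate expected fraction of masked assessments;
#'   default 0.10.
#' @param sensing_missing_rate expected fraction of masked sensing values;
#'   default 0.091.
#' @param mar_slope slope of the logistic missingness model on the
#'   standardized usage-frequency driver; default 1.5.
#' @param seed root seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 55, study_days = 30,
                          assessment_days = c(1, 16, 31),
                          planted_betas = list(),
                          between_person_sd = 0.6, within_person_sd = 0.8,
                          feature_cor = 0, outcome_icc = 0.4,
                          slope_sd = 0.1,
                          dass_missing_rate = 0.10,
                          sensing_missing_rate = 0.091,
                          mar_slope = 1.5, seed = 1L) {
  stopifnot(n_participants >= 2,
            dass_missing_rate >= 0, dass_missing_rate <= 1,
            sensing_missing_rate >= 0, sensing_missing_rate <= 1,
            feature_cor >= 0, feature_cor < 1)
  known <- names(feature_clusters())
  for (oc in names(planted_betas)) {
    stopifnot(oc %in% c("depression", "anxiety", "stress"))
    bad <- setdiff(names(planted_betas[[oc]]), known)
    if (length(bad)) {
      stop("unrecognized feature name(s) in planted_betas$", oc, ": ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(
    n_participants = n_participants, study_days = study_days,
    assessment_days = assessment_days, planted_betas = planted_betas,
    between_person_sd = between_person_sd,
    within_person_sd = within_person_sd, feature_cor = feature_cor,
    outcome_icc = outcome_icc, slope_sd = slope_sd,
    dass_missing_rate = dass_missing_rate,
    sensing_missing_rate = sensing_missing_rate,
    mar_slope = mar_slope, seed = seed
  ), class = "cohort_config")
}

# logistic intercept such that E[plogis(a + s Z)] = rate for Z ~ N(0,1)
mar_intercept <- function(rate, slope) {
  if (rate <= 0) return(-Inf)
  if (rate >= 1) return(Inf)
  f <- function(a) {
    z <- seq(-6, 6, length.out = 2001)
    w <- stats::dnorm(z)
    sum(stats::plogis(a + slope * z) * w) / sum(w) - rate
  }
  stats::uniroot(f, c(-20, 20))$root
}

#' Simulate a window-level model table with planted effects
#'
#' The fast path of the cohort generator: draws the standardized
#' participant-window features directly from the latent model (person
#' component + window component, optionally correlated across features via
#' a common factor), builds each outcome as the planted linear combination
#' of the *noiseless* features plus a person random intercept, person
#' random slopes and residual noise, and applies MAR masking. Residual
#' variance is set so each outcome has unit total variance, which keeps the
#' planted slopes on the standardized scale the analysis estimates.
#'
#' Masking is missing at random by construction: the probability is a
#' deterministic logistic function of the observed usage-frequency
#' covariate. DASS outcomes are masked at `dass_missing_rate`; sensing
#' features other than the driver at `sensing_missing_rate`.
#'
#' @param config a [cohort_config()].
#' @param n_windows windows per participant; default 2.
#' @param features feature columns to generate; default the canonical 16.
#' @return List: `table` (with NAs), `complete` (before masking), `truth`
#'   (planted betas, implied single-predictor slopes, person intercepts and
#'   realized slopes, variance components).
#' @export
simulate_model_table <- function(config, n_windows = 2,
                                 features = names(feature_clusters())) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  nf <- length(features)
  rho <- config$feature_cor
  sb <- config$between_person_sd
  sw <- config$within_person_sd
  tot_sd <- sqrt(sb^2 + sw^2)
  outcomes <- c("depression", "anxiety", "stress")

  with_seed(derive_seed(config$seed, "model-table"), {
    # features: common factor induces exchangeable correlation rho
    g_p <- matrix(rep(stats::rnorm(n, sd = sb), each = nf), nrow = n,
                  byrow = TRUE)
    g_w <- stats::rnorm(n * n_windows, sd = sw)
    X <- matrix(NA_real_, n * n_windows, nf,
                dimnames = list(NULL, features))
    a_p <- matrix(stats::rnorm(n * nf, sd = sb), n, nf)
    row_idx <- rep(seq_len(n), each = n_windows)
    for (f in seq_len(nf)) {
      e_w <- stats::rnorm(n * n_windows, sd = sw)
      person <- sqrt(rho) * g_p[, f] + sqrt(1 - rho) * a_p[, f]
      window <- sqrt(rho) * g_w + sqrt(1 - rho) * e_w
      X[, f] <- (person[row_idx] + window) / tot_sd   # unit variance
    }

    tab <- data.frame(participant = sprintf("P%03d", row_idx),
                      window = rep(seq_len(n_windows), times = n),
                      X, stringsAsFactors = FALSE)

    Sigma <- matrix(rho, nf, nf,
                    dimnames = list(features, features))
    diag(Sigma) <- 1
    truth <- list(betas = list(), implied_marginal = list(),
                  intercepts = list(), slopes = list(),
                  varcomp = list())
    for (oc in outcomes) {
      b <- stats::setNames(rep(0, nf), features)
      pb <- config$planted_betas[[oc]]
      if (!is.null(pb)) b[names(pb)] <- pb
      explained <- as.numeric(t(b) %*% Sigma %*% b) +
        config$slope_sd^2 * sum(b != 0)
      resid_total <- max(1 - explained, 0.1)
      s_u <- sqrt(config$outcome_icc * resid_total)
      s_e <- sqrt((1 - config$outcome_icc) * resid_total)
      u <- stats::rnorm(n, sd = s_u)
      active <- names(b)[b != 0]
      bi <- matrix(rep(b[active], each = n), n, length(active),
                   dimnames = list(NULL, active))
      if (length(active)) {
        bi <- bi + matrix(stats::rnorm(n * length(active),
                                       sd = config$slope_sd),
                          n, length(active))
      }
      y <- as.numeric(X %*% b) + u[row_idx] + stats::rnorm(n * n_windows,
                                                           sd = s_e)
      if (length(active)) {
        dev <- bi[row_idx, , drop = FALSE] -
          matrix(rep(b[active], each = n * n_windows), n * n_windows,
                 length(active))
        y <- y + rowSums(X[, active, drop = FALSE] * dev)
      }
      tab[[oc]] <- y
      truth$betas[[oc]] <- b
      truth$implied_marginal[[oc]] <- as.numeric(Sigma %*% b)
      names(truth$implied_marginal[[oc]]) <- features
      truth$intercepts[[oc]] <- u
      truth$slopes[[oc]] <- bi
      truth$varcomp[[oc]] <- c(intercept_sd = s_u, residual_sd = s_e)
    }
    complete <- tab

    # MAR masking driven by observed usage frequency (never masked itself)
    driver <- if ("usage_frequency" %in% features) {
      tab$usage_frequency
    } else {
      rep(0, nrow(tab))
    }
    if (config$dass_missing_rate > 0) {
      a <- mar_intercept(config$dass_missing_rate, config$mar_slope)
      pmask <- stats::plogis(a + config$mar_slope * driver)
      for (oc in outcomes) {
        tab[[oc]][stats::runif(nrow(tab)) < pmask] <- NA_real_
      }
    }
    sensing <- intersect(features, names(feature_clusters())[
      feature_clusters() %in% c("GPS", "usage", "wearable")])
    sensing <- setdiff(sensing, "usage_frequency")
    if (config$sensing_missing_rate > 0 && length(sensing)) {
      a <- mar_intercept(config$sensing_missing_rate, config$mar_slope)
      pmask <- stats::plogis(a + config$mar_slope * driver)
      for (f in sensing) {
        tab[[f]][stats::runif(nrow(tab)) < pmask] <- NA_real_
      }
    }
    list(table = tab, complete = complete, truth = truth)
  })
}

#' Implied single-predictor slopes under correlated features
#'
#' With exchangeable feature correlation `rho` and planted direct slopes
#' `b`, the population slope of a single-predictor regression on feature f
#' is `(Sigma b)_f = b_f + rho * sum(b_-f)`. This is the reference truth
#' for single-predictor recovery under correlated designs.
#'
#' @param betas named numeric vector of direct slopes.
#' @param feature_cor exchangeable correlation.
#' @return Named vector of implied marginal slopes.
#' @export
implied_slopes <- function(betas, feature_cor = 0) {
  out <- vapply(seq_along(betas), function(i) {
    unname(betas[i]) + feature_cor * sum(betas[-i])
  }, 0)
  stats::setNames(out, names(betas))
}
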