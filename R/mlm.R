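# Linear mixed models: repeated windows (level 1) nested in participants
# (level 2), random intercepts and (uncorrelated) random slopes, maximum
# likelihood, Satterthwaite fixed-effect df.

#' Fit a random-intercept / random-slope linear mixed model
#'
#' Fits `outcome ~ predictors` with a per-participant random intercept and,
#' by default, an uncorrelated random slope for each predictor (with at most
#' two observations per participant a full random-effects covariance is not
#' identifiable). Estimation is maximum likelihood (`REML = FALSE`), as
#' required for likelihood-ratio comparison of nested fixed-effect
#' structures. If the fit is singular — a random-effect variance on the zero
#' boundary — the model is refit with a random intercept only and flagged.
#' Fixed-effect df use the Satterthwaite approximation.
#'
#' @param table model table (typically standardized); must contain
#'   `participant`, the outcome and the predictors.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor columns (empty for the
#'   intercept-only baseline).
#' @param random_slopes predictors receiving random slopes; default all of
#'   `predictors`.
#' @param reml fit by REML instead of ML; default FALSE (ML).
#' @param df_method `"satterthwaite"` (default) or `"residual"` (`n - p`;
#'   cheaper, appropriate when the fit's own df are not consumed, e.g. for
#'   per-imputation fits pooled with Barnard-Rubin df).
#' @return An object of class `mlm_fit`: list with `coefficients` (term,
#'   estimate, se, df, t, p), `varcomp` (named SDs: intercept, per-slope,
#'   residual), `logLik`, `deviance`, `converged`, `boundary_refit`,
#'   `formula`, `n`, `n_participants`, and the underlying `lmerMod` in
#'   `$fit`.
#' @export
fit_mlm <- function(table, outcome, predictors = character(0),
                    random_slopes = predictors, reml = FALSE,
                    df_method = c("satterthwaite", "residual")) {
  df_method <- match.arg(df_method)
  stopifnot("participant" %in% names(table), outcome %in% names(table),
            all(predictors %in% names(table)))
  use <- stats::complete.cases(table[c(outcome, predictors)])
  d <- table[use, , drop = FALSE]
  if (length(unique(d$participant)) < 2) {
    stop("need observations from at least 2 participants")
  }
  fe <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  re <- "(1 | participant)"
  if (length(random_slopes)) {
    re <- paste(c(re, sprintf("(0 + %s | participant)", random_slopes)),
                collapse = " + ")
  }
  fml <- stats::as.formula(paste(outcome, "~", fe, "+", re))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = TRUE)
  # Satterthwaite df via lmerTest; degenerate fits (e.g. zero residual
  # variance) fall back to plain lme4 with residual df
  do_fit <- function(f) {
    if (df_method == "satterthwaite") {
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lmerTest::lmer(f, data = d, REML = reml, control = ctrl))),
        error = function(e) NULL)
      if (!is.null(fit)) return(list(fit = fit, satt = TRUE))
    }
    list(fit = suppressMessages(suppressWarnings(
      lme4::lmer(f, data = d, REML = reml, control = ctrl))), satt = FALSE)
  }
  ft <- do_fit(fml)
  boundary_refit <- FALSE
  if (length(random_slopes) && lme4::isSingular(ft$fit, tol = 1e-5)) {
    fml2 <- stats::as.formula(paste(outcome, "~", fe, "+ (1 | participant)"))
    ft <- do_fit(fml2)
    boundary_refit <- TRUE
    fml <- fml2
  }
  fit <- ft$fit
  conv <- is.null(fit@optinfo$conv$lme4$messages)
  cs <- tryCatch(suppressWarnings(as.data.frame(coef(summary(fit)))),
                 error = function(e) NULL)
  if (is.null(cs)) {
    # degenerate covariance (e.g. zero residual variance in a noiseless
    # limit): report estimates, leave inference columns NA
    est <- lme4::fixef(fit)
    se <- tryCatch(suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit))))),
                   error = function(e) rep(NA_real_, length(est)))
    cs <- data.frame(Estimate = est, `Std. Error` = se,
                     `t value` = est / se, check.names = FALSE)
  }
  if (!("df" %in% names(cs))) {
    cs$df <- nrow(d) - nrow(cs)
    cs$`Pr(>|t|)` <- 2 * stats::pt(-abs(cs[, "t value"]), cs$df)
  }
  coefs <- data.frame(term = rownames(cs), estimate = cs[, "Estimate"],
                      se = cs[, "Std. Error"], df = cs[, "df"],
                      t = cs[, "t value"], p = cs[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sds <- stats::setNames(vc$sdcor, ifelse(is.na(vc$var1), "residual",
                                          vc$var1))
  names(sds)[names(sds) == "(Intercept)"] <- "intercept"
  structure(list(
    coefficients = coefs,
    varcomp = sds,
    logLik = as.numeric(stats::logLik(fit)),
    deviance = -2 * as.numeric(stats::logLik(fit)),
    converged = conv,
    boundary_refit = boundary_refit,
    formula = fml,
    outcome = outcome,
    predictors = predictors,
    random_slopes = if (boundary_refit) character(0) else random_slopes,
    n = nrow(d),
    n_participants = length(unique(d$participant)),
    reml = reml,
    fit = fit
  ), class = "mlm_fit")
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat("Linear mixed model (", if (x$reml) "REML" else "ML", "): ",
      deparse(x$formula), "\n", sep = "")
  cat(x$n, "observations,", x$n_participants, "participants; logLik",
      format(x$logLik, digits = 6), "\n")
  if (x$boundary_refit) {
    cat("note: random-slope variance on boundary; refit with random",
        "intercept only\n")
  }
  printCoefmat(as.matrix(x$coefficients[, c("estimate", "se", "df", "t", "p")],
                         rownames.force = TRUE),
               P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
summary.mlm_fit <- function(object, ...) {
  object
}

#' @export
coef.mlm_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.mlm_fit <- function(object, ...) {
  stats::logLik(object$fit)
}

# Refit a model with fixed effects constrained to given values, estimating
# only the variance components (used by the pooled likelihood-ratio test:
# the constrained log-likelihood is evaluated at the averaged estimates).
constrained_loglik <- function(fit_obj, beta) {
  d <- fit_obj$fit@frame
  X <- stats::model.matrix(fit_obj$fit)
  stopifnot(ncol(X) == length(beta))
  d$`.offset.` <- as.numeric(X %*% beta)
  re <- "(1 | participant)"
  if (length(fit_obj$random_slopes)) {
    re <- paste(c(re, sprintf("(0 + %s | participant)",
                              fit_obj$random_slopes)),
                collapse = " + ")
  }
  fml <- stats::as.formula(paste(fit_obj$outcome,
                                 "~ 0 + offset(`.offset.`) +", re))
  m <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = d, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  as.numeric(stats::logLik(m))
}
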