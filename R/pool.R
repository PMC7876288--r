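# Rubin's rules for pooling estimates over multiply imputed datasets, and
# the pooled likelihood-ratio test (the D3 statistic) for comparing nested
# mixed models across imputations.

#' Pool mixed-model fits with Rubin's rules
#'
#' Estimates are averaged over the `m` fits; the total variance of each
#' coefficient is `W + (1 + 1/m) B` with `W` the mean within-imputation
#' variance and `B` the between-imputation variance. Degrees of freedom use
#' the Barnard-Rubin small-sample adjustment with the complete-data df
#' taken as `n - p`.
#'
#' @param fits list of [fit_mlm()] objects sharing one model formula.
#' @return Object of class `pooled_fit`: `coefficients` (term, estimate,
#'   se, df, t, p, riv, fmi), `m`, `W`, `B` (named vectors), plus the
#'   formula metadata of the first fit.
#' @export
pool_rubin <- function(fits) {
  if (length(fits) == 0) stop("no fits to pool (m = 0)")
  terms0 <- fits[[1]]$coefficients$term
  same <- vapply(fits, function(f) identical(f$coefficients$term, terms0),
                 TRUE)
  if (!all(same)) stop("all fits must share the same model formula")
  m <- length(fits)
  Q <- vapply(fits, function(f) f$coefficients$estimate,
              numeric(length(terms0)))
  U <- vapply(fits, function(f) f$coefficients$se^2,
              numeric(length(terms0)))
  Q <- matrix(Q, nrow = length(terms0))
  U <- matrix(U, nrow = length(terms0))
  qbar <- rowMeans(Q)
  W <- rowMeans(U)
  B <- if (m > 1) apply(Q, 1, stats::var) else rep(0, length(terms0))
  Tvar <- W + (1 + 1 / m) * B
  se <- sqrt(Tvar)
  riv <- ifelse(W > 0, (1 + 1 / m) * B / W, 0)
  lambda <- (1 + 1 / m) * B / Tvar
  lambda[Tvar == 0] <- 0
  dfcom <- fits[[1]]$n - length(terms0)
  if (m > 1) {
    dfold <- ifelse(lambda > 0, (m - 1) / lambda^2, Inf)
    dfobs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df <- ifelse(is.finite(dfold), dfold * dfobs / (dfold + dfobs), dfobs)
  } else {
    # single dataset: fall back to the per-fit (Satterthwaite) df
    df <- fits[[1]]$coefficients$df
  }
  tval <- ifelse(se > 0, qbar / se, NA_real_)
  p <- 2 * stats::pt(-abs(tval), df = df)
  fmi <- (riv + 2 / (df + 3)) / (1 + riv)
  structure(list(
    coefficients = data.frame(term = terms0, estimate = qbar, se = se,
                              df = df, t = tval, p = p, riv = riv,
                              fmi = fmi, row.names = NULL,
                              stringsAsFactors = FALSE),
    m = m,
    W = stats::setNames(W, terms0),
    B = stats::setNames(B, terms0),
    outcome = fits[[1]]$outcome,
    predictors = fits[[1]]$predictors,
    formula = fits[[1]]$formula,
    n = fits[[1]]$n,
    boundary_refit = any(vapply(fits, function(f) f$boundary_refit, TRUE))
  ), class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat("Rubin-pooled mixed model over m =", x$m, "imputations:",
      deparse(x$formula), "\n")
  printCoefmat(as.matrix(x$coefficients[, c("estimate", "se", "df", "t",
                                            "p")]),
               P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.pooled_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.pooled_fit <- function(object, ...) object

#' Pooled likelihood-ratio test for nested mixed models (D3)
#'
#' Combines per-imputation likelihood-ratio statistics into a single F
#' test. Let `dbar` be the mean of the LR statistics evaluated at each
#' dataset's own ML estimates, and `dtilde` the mean of the LR statistics
#' re-evaluated with the fixed effects constrained to their Rubin-pooled
#' values (variance components re-optimized). With `k` constrained
#' parameters the statistic is `F = dtilde / (k (1 + r))`, where
#' `r = (m+1)/(k(m-1)) (dbar - dtilde)` estimates the relative increase in
#' variance. With m = 1 (no missing data) the statistic reduces to the
#' classical LRT: `F = d / k` on `(k, Inf)` df, whose p value equals the
#' chi-square test's.
#'
#' @param null_fits,alt_fits lists of [fit_mlm()] ML fits per completed
#'   dataset; the null model's predictors must nest in the alternative's.
#' @return Object of class `pooled_lrt`: `F`, `df1`, `df2`, `p`, `r`,
#'   `dbar`, `dtilde`, `m`.
#' @export
lrt_pooled <- function(null_fits, alt_fits) {
  stopifnot(length(null_fits) == length(alt_fits), length(alt_fits) >= 1)
  m <- length(alt_fits)
  p0 <- null_fits[[1]]$predictors
  p1 <- alt_fits[[1]]$predictors
  if (!all(p0 %in% p1) || length(p1) <= length(p0)) {
    stop("models are not nested: the null predictors must be a strict ",
         "subset of the alternative's")
  }
  if (null_fits[[1]]$reml || alt_fits[[1]]$reml) {
    stop("likelihood-ratio comparison requires ML fits")
  }
  k <- length(p1) - length(p0)
  d <- vapply(seq_len(m), function(j) {
    2 * (alt_fits[[j]]$logLik - null_fits[[j]]$logLik)
  }, 0)
  dbar <- mean(d)
  if (m == 1) {
    Fstat <- max(dbar, 0) / k
    return(structure(list(F = Fstat, df1 = k, df2 = Inf,
                          p = stats::pf(Fstat, k, Inf, lower.tail = FALSE),
                          r = 0, dbar = dbar, dtilde = dbar, m = 1),
                     class = "pooled_lrt"))
  }
  beta0 <- rowMeans(matrix(vapply(null_fits,
                                  function(f) f$coefficients$estimate,
                                  numeric(length(p0) + 1)),
                           nrow = length(p0) + 1))
  beta1 <- rowMeans(matrix(vapply(alt_fits,
                                  function(f) f$coefficients$estimate,
                                  numeric(length(p1) + 1)),
                           nrow = length(p1) + 1))
  dtilde_j <- vapply(seq_len(m), function(j) {
    2 * (constrained_loglik(alt_fits[[j]], beta1) -
           constrained_loglik(null_fits[[j]], beta0))
  }, 0)
  dtilde <- mean(dtilde_j)
  r <- max(((m + 1) / (k * (m - 1))) * (dbar - dtilde), 0)
  Fstat <- max(dtilde, 0) / (k * (1 + r))
  km <- k * (m - 1)
  df2 <- if (km > 4) {
    4 + (km - 4) * (1 + (1 - 2 / km) / max(r, 1e-12))^2
  } else {
    km * (1 + 1 / k) * (1 + 1 / max(r, 1e-12))^2 / 2
  }
  structure(list(F = Fstat, df1 = k, df2 = df2,
                 p = stats::pf(Fstat, k, df2, lower.tail = FALSE),
                 r = r, dbar = dbar, dtilde = dtilde, m = m),
            class = "pooled_lrt")
}

#' @export
print.pooled_lrt <- function(x, ...) {
  cat(sprintf("Pooled LRT (D3): F(%d, %s) = %.3f, p = %.4g (m = %d)\n",
              x$df1,
              if (is.finite(x$df2)) format(round(x$df2, 1)) else "Inf",
              x$F, x$p, x$m))
  invisible(x)
}
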