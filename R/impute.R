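# Multilevel predictive-mean-matching multiple imputation by chained
# equations. Each incomplete column is imputed from a two-level linear
# predictor (participant means + within-person deviations of the other
# variables); the imputed value is always an observed donor value.

#' Multilevel predictive-mean-matching multiple imputation
#'
#' Chained-equations imputation honouring the two-level structure
#' (windows nested in participants). For each incomplete column, the
#' imputation model regresses the observed values on the participant means
#' and within-person deviations of every other registered variable (a
#' two-level predictor set, so person-level and occasion-level information
#' both inform the imputation). Predictive mean matching, type 1: the
#' linear predictor for the observed cases uses the least-squares
#' coefficients and the one for the missing cases uses a Bayesian draw of
#' the coefficients; each missing case then copies the observed value of
#' one donor drawn at random from the `donors` closest predicted values.
#' The chained loop sweeps all incomplete columns `iterations` times per
#' chain; `m` independent chains give `m` completed tables. Per-iteration
#' chain means and SDs of the imputed values are retained so convergence
#' can be inspected.
#'
#' @param table model table (data.frame) with `participant` and numeric
#'   analysis columns; `window` is carried along untouched.
#' @param m number of completed datasets; default 20.
#' @param iterations chained-equation sweeps per chain; default 15.
#' @param donors donor-pool size; default 5.
#' @param seed integer seed; chains derive independent sub-seeds.
#' @param impute_cols columns eligible for imputation; default every
#'   incomplete numeric column except `participant` / `window`.
#' @param predictors columns used as regressors (auxiliaries included);
#'   default all numeric columns except `participant` / `window`.
#' @return An object of class `imputation_set`: `tables` (list of m
#'   completed data.frames), `chain_stats` (data.frame: chain, iteration,
#'   column, mean, sd of the imputed entries), `m`, `iterations`, `donors`,
#'   `seed`, `impute_cols`.
#' @export
impute_mpmm <- function(table, m = 20, iterations = 15, donors = 5,
                        seed = 1L, impute_cols = NULL, predictors = NULL) {
  stopifnot(m >= 1, iterations >= 1, donors >= 1,
            "participant" %in% names(table))
  num <- names(table)[vapply(table, is.numeric, TRUE)]
  num <- setdiff(num, c("participant", "window"))
  if (is.null(predictors)) predictors <- num
  if (is.null(impute_cols)) {
    impute_cols <- num[vapply(num, function(cn) anyNA(table[[cn]]), TRUE)]
  }
  all_missing <- impute_cols[vapply(impute_cols,
                                    function(cn) all(is.na(table[[cn]])),
                                    TRUE)]
  if (length(all_missing)) {
    stop("column(s) entirely missing, nothing to match on: ",
         paste(all_missing, collapse = ", "))
  }
  miss <- lapply(impute_cols, function(cn) which(is.na(table[[cn]])))
  names(miss) <- impute_cols
  impute_cols <- impute_cols[lengths(miss) > 0]
  miss <- miss[impute_cols]

  pid <- factor(table$participant)
  pid_idx <- as.integer(pid)
  pid_n <- tabulate(pid_idx)
  pmean <- function(v) {
    m <- rowsum(v, pid_idx, reorder = TRUE) / pid_n
    m[pid_idx]
  }
  build_X <- function(d, ycol) {
    regs <- setdiff(predictors, ycol)
    X <- matrix(1, nrow(d), 1 + 2 * length(regs))
    j <- 1L
    for (v in regs) {
      mv <- pmean(d[[v]])
      X[, j + 1L] <- mv
      X[, j + 2L] <- d[[v]] - mv
      j <- j + 2L
    }
    # drop constant (zero-variance) regressors beyond the intercept
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                          function(col) stats::sd(col) > 0))
    X[, keep, drop = FALSE]
  }

  chain_stats <- list()
  tables <- vector("list", m)
  for (chain in seq_len(m)) {
    d <- table
    with_seed(derive_seed(seed, paste0("mpmm-chain-", chain)), {
      # initial fill: random draws from each column's observed values
      for (cn in impute_cols) {
        obs <- d[[cn]][-miss[[cn]]]
        d[[cn]][miss[[cn]]] <- sample(obs, length(miss[[cn]]),
                                      replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (cn in impute_cols) {
          idx_mis <- miss[[cn]]
          idx_obs <- setdiff(seq_len(nrow(d)), idx_mis)
          X <- build_X(d, cn)
          Xo <- X[idx_obs, , drop = FALSE]
          yo <- d[[cn]][idx_obs]
          qr_ <- qr(Xo)
          beta_hat <- qr.coef(qr_, yo)
          beta_hat[is.na(beta_hat)] <- 0
          resid <- yo - as.numeric(Xo %*% beta_hat)
          df_res <- max(length(yo) - qr_$rank, 1)
          sigma2 <- sum(resid^2) / stats::rchisq(1, df_res)
          R <- qr.R(qr_)
          # Bayesian coefficient draw (guarded for rank deficiency)
          beta_star <- tryCatch({
            V <- chol2inv(R)
            beta_hat + as.numeric(t(chol(V)) %*% stats::rnorm(ncol(Xo))) *
              sqrt(sigma2)
          }, error = function(e) beta_hat)
          yhat_obs <- as.numeric(Xo %*% beta_hat)
          yhat_mis <- as.numeric(X[idx_mis, , drop = FALSE] %*% beta_star)
          nd <- min(donors, length(idx_obs))
          imp <- vapply(yhat_mis, function(ym) {
            pool <- order(abs(yhat_obs - ym))[seq_len(nd)]
            yo[pool[sample.int(nd, 1)]]
          }, 0)
          d[[cn]][idx_mis] <- imp
          chain_stats[[length(chain_stats) + 1L]] <- data.frame(
            chain = chain, iteration = it, column = cn,
            mean = mean(imp), sd = stats::sd(imp),
            stringsAsFactors = FALSE)
        }
      }
    })
    tables[[chain]] <- d
  }
  structure(list(
    tables = tables,
    chain_stats = if (length(chain_stats)) do.call(rbind, chain_stats)
      else data.frame(),
    m = m, iterations = iterations, donors = donors, seed = seed,
    impute_cols = impute_cols
  ), class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> m =", x$m, "chains,", x$iterations,
      "iterations, donors =", x$donors, "\n")
  if (length(x$impute_cols)) {
    cat("imputed columns:", paste(x$impute_cols, collapse = ", "), "\n")
  } else {
    cat("no missing values; completed tables equal the input\n")
  }
  invisible(x)
}
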