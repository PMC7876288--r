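# Spearman correlations with cluster-wise Holm adjustment, and the
# intraclass correlation that motivates the multilevel models.

#' Spearman correlations with cluster-wise Holm adjustment
#'
#' For every feature x outcome pair: Spearman's rho computed as the Pearson
#' correlation of mid-ranks (average ties), with the t approximation for
#' the p value. Because blanket adjustment over-corrects in exploratory
#' settings, the Holm step-down runs separately within each feature-cluster
#' x outcome family (e.g. the five GPS features against depression form one
#' family).
#'
#' @param table model table with feature and outcome columns (rows =
#'   participant-windows); missing pairs are dropped pairwise.
#' @param outcomes outcome column names; default
#'   `c("depression", "anxiety", "stress")`.
#' @param clusters named cluster map as from [feature_clusters()]; only
#'   features present in `table` are used.
#' @param min_pairs minimum complete pairs; below it the result row is NA.
#' @return data.frame with `feature`, `cluster`, `outcome`, `n`, `rho`,
#'   `p_raw`, `p_adjusted`.
#' @export
spearman_with_holm <- function(table,
                               outcomes = c("depression", "anxiety", "stress"),
                               clusters = feature_clusters(),
                               min_pairs = 3) {
  feats <- intersect(names(clusters), names(table))
  grid <- expand.grid(feature = feats, outcome = outcomes,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- table[[grid$feature[i]]]
    y <- table[[grid$outcome[i]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_pairs) {
      return(data.frame(feature = grid$feature[i],
                        cluster = unname(clusters[grid$feature[i]]),
                        outcome = grid$outcome[i], n = n, rho = NA_real_,
                        p_raw = NA_real_, stringsAsFactors = FALSE))
    }
    rho <- stats::cor(rank(x[ok]), rank(y[ok]))
    p <- if (abs(rho) >= 1) 0 else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tval), df = n - 2)
    }
    data.frame(feature = grid$feature[i],
               cluster = unname(clusters[grid$feature[i]]),
               outcome = grid$outcome[i], n = n, rho = rho, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- NA_real_
  for (cl in unique(out$cluster)) {
    for (oc in outcomes) {
      sel <- out$cluster == cl & out$outcome == oc & !is.na(out$p_raw)
      out$p_adjusted[sel] <- stats::p.adjust(out$p_raw[sel], method = "holm")
    }
  }
  out
}

#' Intraclass correlation, ICC(1,1)
#'
#' One-way random-effects ANOVA estimator: between-person variance over
#' total variance, with the unbalanced-design group size
#' `k0 = (N - sum(n_i^2)/N) / (I - 1)`. Negative between-variance estimates
#' floor the ICC at 0.
#'
#' @param y numeric outcome vector.
#' @param group grouping factor (participant).
#' @return The ICC in `[0, 1]`, or NA for degenerate groupings (fewer than
#'   2 groups with data, or fewer than 2 observations in every group).
#' @export
icc <- function(y, group) {
  ok <- !is.na(y) & !is.na(group)
  y <- y[ok]
  group <- droplevels(factor(group[ok]))
  ni <- tabulate(group)
  I <- nlevels(group)
  N <- length(y)
  if (I < 2 || N <= I) return(NA_real_)
  gm <- mean(y)
  mi <- tapply(y, group, mean)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((y - mi[group])^2)
  msb <- ssb / (I - 1)
  msw <- ssw / (N - I)
  k0 <- (N - sum(ni^2) / N) / (I - 1)
  sb2 <- max((msb - msw) / k0, 0)
  sb2 / (sb2 + msw)
}
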