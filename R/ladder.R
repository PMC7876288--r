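# The combined-model build: screen every feature in a single-predictor
# multilevel model, then assemble a ladder of cluster models (baseline,
# EMA, GPS, GPS+wearable, combined) compared by pooled likelihood-ratio
# tests.

#' Build the single-predictor to combined-model ladder
#'
#' Stage 1 fits a separate multilevel model per feature (random intercept +
#' random slope) and keeps the pooled two-sided p value of its slope. Stage
#' 2 assembles the ladder: intercept-only baseline; EMA model; GPS model;
#' extended digital-phenotyping model (GPS + wearable); combined model
#' (EMA + GPS + wearable) — each stage containing only the predictors whose
#' single-predictor pooled p fell below `alpha` within its cluster(s).
#' Phone-usage features are screened and reported but have no dedicated
#' ladder stage. Empty stages are recorded as "No predictors identified",
#' never skipped. Consecutive non-empty stages are compared with the pooled
#' likelihood-ratio test against the baseline, and the combined model
#' additionally against the EMA and extended stages when those exist.
#'
#' @param imputations an `imputation_set` from [impute_mpmm()], or a single
#'   complete data.frame (treated as m = 1).
#' @param outcome outcome column name (e.g. `"depression"`).
#' @param alpha screening threshold on the pooled p; default 0.05.
#' @param features candidate features; default the canonical 16 present in
#'   the table.
#' @return Object of class `model_ladder`: `outcome`, `single` (screening
#'   data.frame: feature, cluster, estimate, se, df, t, p, significant),
#'   `stages` (named list with `predictors` and `pooled` fit or NULL), and
#'   `comparisons` (data.frame of pooled LRT rows).
#' @export
build_model_ladder <- function(imputations, outcome, alpha = 0.05,
                               features = NULL) {
  tables <- if (inherits(imputations, "imputation_set")) {
    imputations$tables
  } else {
    list(imputations)
  }
  clmap <- feature_clusters()
  if (is.null(features)) {
    features <- intersect(names(clmap), names(tables[[1]]))
  }
  # per-imputation df are not consumed when m > 1 (Barnard-Rubin df take
  # over in pooling), so skip the Satterthwaite computation there
  dfm <- if (length(tables) > 1) "residual" else "satterthwaite"
  fit_all <- function(predictors) {
    lapply(tables, function(tb) fit_mlm(tb, outcome, predictors,
                                        df_method = dfm))
  }
  pooled_of <- function(predictors) {
    fits <- fit_all(predictors)
    list(fits = fits, pooled = pool_rubin(fits))
  }

  single <- lapply(features, function(f) {
    pf <- pooled_of(f)$pooled
    row <- pf$coefficients[pf$coefficients$term == f, ]
    data.frame(feature = f, cluster = unname(clmap[f]),
               estimate = row$estimate, se = row$se, df = row$df,
               t = row$t, p = row$p, stringsAsFactors = FALSE)
  })
  single <- do.call(rbind, single)
  single$significant <- !is.na(single$p) & single$p < alpha
  sig_in <- function(clusters) {
    single$feature[single$significant & single$cluster %in% clusters]
  }

  stage_defs <- list(
    baseline = character(0),
    EMA = sig_in("EMA"),
    GPS = sig_in("GPS"),
    extended = sig_in(c("GPS", "wearable")),
    combined = sig_in(c("EMA", "GPS", "wearable"))
  )
  stages <- list()
  for (nm in names(stage_defs)) {
    preds <- stage_defs[[nm]]
    if (nm != "baseline" && length(preds) == 0) {
      stages[[nm]] <- list(predictors = character(0), pooled = NULL,
                           fits = NULL)
    } else {
      pw <- pooled_of(preds)
      stages[[nm]] <- list(predictors = preds, pooled = pw$pooled,
                           fits = pw$fits)
    }
  }

  comparisons <- list()
  add_cmp <- function(label, null_stage, alt_stage) {
    nf <- stages[[null_stage]]$fits
    af <- stages[[alt_stage]]$fits
    if (is.null(nf) || is.null(af)) return()
    if (length(stages[[alt_stage]]$predictors) <=
        length(stages[[null_stage]]$predictors)) return()
    if (!all(stages[[null_stage]]$predictors %in%
             stages[[alt_stage]]$predictors)) return()
    lrt <- lrt_pooled(nf, af)
    comparisons[[length(comparisons) + 1L]] <<- data.frame(
      comparison = label, F = lrt$F, df1 = lrt$df1, df2 = lrt$df2,
      p = lrt$p, stringsAsFactors = FALSE)
  }
  for (nm in setdiff(names(stages), "baseline")) {
    add_cmp(paste(nm, "vs baseline"), "baseline", nm)
  }
  add_cmp("combined vs EMA", "EMA", "combined")
  add_cmp("combined vs extended", "extended", "combined")
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
    else data.frame(comparison = character(0), F = numeric(0),
                    df1 = numeric(0), df2 = numeric(0), p = numeric(0))

  structure(list(outcome = outcome, alpha = alpha, single = single,
                 stages = stages, comparisons = comparisons,
                 m = length(tables)),
            class = "model_ladder")
}

#' @export
print.model_ladder <- function(x, digits = 3, ...) {
  cat("Model comparison ladder for outcome:", x$outcome,
      sprintf("(m = %d imputations, screening alpha = %g)\n\n",
              x$m, x$alpha))
  labels <- c(baseline = "Baseline model",
              EMA = "EMA model",
              GPS = "GPS model",
              extended = "Extended digital phenotyping model: GPS and wearable data",
              combined = "Combined model: EMA and digital phenotyping model")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat("--", labels[[nm]], "--\n")
    if (is.null(st$pooled)) {
      cat("No predictors identified\n\n")
      next
    }
    cf <- st$pooled$coefficients
    tab <- data.frame(Estimate = round(cf$estimate, digits),
                      SE = round(cf$se, digits),
                      t = round(cf$t, 2), Df = round(cf$df, 0),
                      p = signif(cf$p, 3), row.names = cf$term)
    print(tab)
    cmp <- x$comparisons[grepl(paste0("^", nm, " "), x$comparisons$comparison), ]
    if (nrow(cmp)) {
      cat(sprintf("vs baseline: F(%d, %s) = %.2f, p = %.4g\n",
                  cmp$df1[1],
                  if (is.finite(cmp$df2[1])) format(round(cmp$df2[1], 0))
                  else "Inf",
                  cmp$F[1], cmp$p[1]))
    }
    cat("\n")
  }
  extra <- x$comparisons[grepl("^combined vs", x$comparisons$comparison), ]
  if (nrow(extra)) {
    cat("Additional comparisons:\n")
    print(data.frame(F = round(extra$F, 2), df1 = extra$df1,
                     df2 = round(extra$df2, 0), p = signif(extra$p, 3),
                     row.names = extra$comparison))
  }
  invisible(x)
}
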