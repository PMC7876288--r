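# Study-day alignment, two-week window pooling, and z-standardization of
# the model table (one row per participant x window).

#' The canonical feature set and its cluster map
#'
#' Sixteen daily features in four clusters: GPS mobility (5), phone usage
#' (2), wearable (7) and momentary mood (2).
#'
#' @return Named character vector: names are feature names, values are the
#'   cluster labels (`GPS`, `usage`, `wearable`, `EMA`).
#' @export
feature_clusters <- function() {
  c(total_distance = "GPS", location_variance = "GPS", entropy = "GPS",
    normalized_entropy = "GPS", homestay = "GPS",
    usage_duration = "usage", usage_frequency = "usage",
    steps = "wearable", met_avg = "wearable", tst = "wearable",
    sol = "wearable", waso = "wearable", tib = "wearable",
    hrv_rmssd = "wearable",
    valence = "EMA", arousal = "EMA")
}

#' Map local calendar dates to study days
#'
#' Study day 1 is the participant's enrollment date; the study window spans
#' days 1..`n_days`. Dates outside the window are dropped and counted.
#'
#' @param dates vector of `Date`s.
#' @param enrollment the participant's enrollment `Date`.
#' @param n_days length of the study window; default 30.
#' @return Integer study days (NA for out-of-window dates), with a
#'   `dropped` attribute counting them.
#' @export
to_study_days <- function(dates, enrollment, n_days = 30) {
  day <- as.integer(dates - as.Date(enrollment)) + 1L
  out <- ifelse(day >= 1L & day <= n_days, day, NA_integer_)
  attr(out, "dropped") <- sum(is.na(out) & !is.na(dates))
  out
}

#' Pool daily features into assessment windows
#'
#' Window 1 covers study days 1-15 and pairs with the midpoint assessment
#' (T1, day 16); window 2 covers days 16-30 and pairs with the endpoint
#' (T2, day 31). A window feature is the mean over that window's defined
#' daily values; with fewer than `min_coverage` defined days it is NA.
#'
#' @param daily data.frame with `participant`, `study_day` and feature
#'   columns (see [feature_clusters()]).
#' @param windows list of integer day vectors; default `list(1:15, 16:30)`.
#' @param min_coverage minimum defined days per window; default 5.
#' @param features feature column names; default the canonical 16 (missing
#'   columns are skipped).
#' @return data.frame with one row per participant x window: `participant`,
#'   `window` (1-based index) and the pooled features.
#' @export
pool_windows <- function(daily, windows = list(1:15, 16:30),
                         min_coverage = 5,
                         features = names(feature_clusters())) {
  features <- intersect(features, names(daily))
  rows <- list()
  for (p in unique(daily$participant)) {
    dp <- daily[daily$participant == p, , drop = FALSE]
    for (wi in seq_along(windows)) {
      dw <- dp[dp$study_day %in% windows[[wi]], , drop = FALSE]
      vals <- vapply(features, function(f) {
        v <- dw[[f]]
        v <- v[!is.na(v)]
        if (length(v) >= min_coverage) mean(v) else NA_real_
      }, 0)
      rows[[length(rows) + 1L]] <- c(list(participant = p, window = wi),
                                     as.list(vals))
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' z-standardize the model table
#'
#' Centers and scales each named column by its grand mean and SD over all
#' observed participant-window rows (outcomes included, which is why the
#' fitted intercepts are 0 by construction). Transform parameters are
#' stored for inverse mapping; zero-SD columns are left unscaled and
#' flagged.
#'
#' @param table the pooled model table.
#' @param columns columns to standardize; default every numeric column
#'   except `participant` and `window`.
#' @return The table with standardized columns; attributes `scaling` (a
#'   data.frame of column/mean/sd) and `degenerate` (zero-SD column names).
#' @export
standardize_model_table <- function(table, columns = NULL) {
  if (is.null(columns)) {
    num <- vapply(table, is.numeric, TRUE)
    columns <- setdiff(names(table)[num], c("participant", "window"))
  }
  scaling <- data.frame(column = character(0), mean = numeric(0),
                        sd = numeric(0), stringsAsFactors = FALSE)
  degenerate <- character(0)
  for (cn in columns) {
    v <- table[[cn]]
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      degenerate <- c(degenerate, cn)
      next
    }
    table[[cn]] <- (v - m) / s
    scaling <- rbind(scaling, data.frame(column = cn, mean = m, sd = s,
                                         stringsAsFactors = FALSE))
  }
  attr(table, "scaling") <- scaling
  attr(table, "degenerate") <- degenerate
  table
}

#' Undo the z-standardization of selected columns
#'
#' @param table a table produced by [standardize_model_table()].
#' @param columns columns to back-transform; default all recorded.
#' @return The table on the original scale for those columns.
#' @export
unstandardize <- function(table, columns = NULL) {
  sc <- attr(table, "scaling")
  stopifnot(!is.null(sc))
  if (is.null(columns)) columns <- sc$column
  for (cn in intersect(columns, sc$column)) {
    r <- sc[sc$column == cn, ]
    table[[cn]] <- table[[cn]] * r$sd + r$mean
  }
  table
}
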