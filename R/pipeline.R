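# Pipeline orchestration: simulate -> extract -> analyze -> report, with
# plain-CSV interchange between stages, a removal/coverage ledger, and a
# run manifest recording configuration and seeds.

aware_screen_codes <- c(off = 0L, on = 1L, locked = 2L, unlocked = 3L)

#' Write a simulated cohort as AWARE-style CSV tables
#'
#' Emits the tables the readers consume: `locations.csv` (timestamp,
#' device_id, double_latitude, double_longitude, accuracy), `screen.csv`
#' (timestamp, device_id, screen_status with 0=off, 1=on, 2=locked,
#' 3=unlocked), `timezone.csv`, `wearable.csv`, `ema.csv`, `dass.csv`,
#' `enrollment.csv`, plus `truth.json` with the planted parameters.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                       row.names = FALSE)
  w(data.frame(timestamp = cohort$gps$timestamp,
               device_id = cohort$gps$participant,
               double_latitude = cohort$gps$latitude,
               double_longitude = cohort$gps$longitude,
               accuracy = cohort$gps$accuracy), "locations.csv")
  w(data.frame(timestamp = cohort$screen$timestamp,
               device_id = cohort$screen$participant,
               screen_status = aware_screen_codes[cohort$screen$status]),
    "screen.csv")
  w(data.frame(timestamp = cohort$timezones$timestamp,
               device_id = cohort$timezones$participant,
               timezone = cohort$timezones$timezone), "timezone.csv")
  w(cohort$wearable, "wearable.csv")
  w(cohort$ema, "ema.csv")
  w(cohort$dass, "dass.csv")
  w(cohort$enrollment, "enrollment.csv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- cohort$truth
    truth$latent_windows <- NULL
    truth$slopes <- lapply(truth$slopes, as.data.frame)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read AWARE-style CSV tables back into a cohort object
#'
#' @param dir directory written by [write_cohort()].
#' @return A list with the same stream tables as a `cohort`.
#' @export
read_cohort <- function(dir) {
  r <- function(f) utils::read.csv(file.path(dir, f),
                                   stringsAsFactors = FALSE)
  loc <- r("locations.csv")
  scr <- r("screen.csv")
  tzs <- r("timezone.csv")
  status <- names(aware_screen_codes)[match(scr$screen_status,
                                            aware_screen_codes)]
  list(
    gps = data.frame(participant = loc$device_id,
                     timestamp = loc$timestamp,
                     latitude = loc$double_latitude,
                     longitude = loc$double_longitude,
                     accuracy = loc$accuracy, stringsAsFactors = FALSE),
    screen = data.frame(participant = scr$device_id,
                        timestamp = scr$timestamp, status = status,
                        stringsAsFactors = FALSE),
    timezones = data.frame(participant = tzs$device_id,
                           timestamp = tzs$timestamp,
                           timezone = tzs$timezone,
                           stringsAsFactors = FALSE),
    wearable = transform(r("wearable.csv"), date = as.Date(date)),
    ema = r("ema.csv"),
    dass = r("dass.csv"),
    enrollment = transform(r("enrollment.csv"), date = as.Date(date))
  )
}

#' Extract the daily feature table from raw streams
#'
#' Runs the full preprocessing chain per participant: localization, trace
#' cleaning against the pooled 80th-percentile accuracy threshold,
#' speed-based state labeling, per-window stay-point clustering, per-day
#' mobility features; screen sessionization and daily usage features;
#' wearable validation; daily mood means. Study days come from each
#' participant's enrollment date.
#'
#' @param streams cohort-like list (`gps`, `screen`, `wearable`, `ema`,
#'   `timezones`, `enrollment`).
#' @param study_days study length; default 30.
#' @param windows day windows for cluster fitting; default
#'   `list(1:15, 16:30)`.
#' @param accuracy_percentile pooled accuracy cut percentile; default 80.
#' @param speed_threshold_kmh,gap_min,max_dist_m,k_max see the stage
#'   functions.
#' @param seed seed for the clustering restarts.
#' @return data.frame of daily feature vectors (participant, study_day,
#'   the 16 features), with a `ledger` attribute summarizing removals.
#' @export
extract_features <- function(streams, study_days = 30,
                             windows = list(1:15, 16:30),
                             accuracy_percentile = 80,
                             speed_threshold_kmh = 1, gap_min = 15,
                             max_dist_m = 500, k_max = 20, seed = 1L) {
  acc_cut <- accuracy_threshold(streams$gps$accuracy, accuracy_percentile)
  pids <- streams$enrollment$participant
  ledger <- c(duplicate = 0L, zero_coord = 0L, accuracy = 0L,
              out_of_window = 0L)
  rows <- list()
  for (p in pids) {
    enroll <- streams$enrollment$date[streams$enrollment$participant == p]
    tzr <- streams$timezones[streams$timezones$participant == p, ]
    gps <- streams$gps[streams$gps$participant == p, , drop = FALSE]
    gps <- localize(gps, tzr)
    gps <- clean_trace(gps, acc_cut)
    ledger[1:3] <- ledger[1:3] + attr(gps, "ledger")
    sd_ <- to_study_days(gps$local_date, enroll, study_days)
    ledger["out_of_window"] <- ledger["out_of_window"] +
      (attr(sd_, "dropped") %||% 0L)
    gps$study_day <- as.integer(sd_)
    gps <- gps[!is.na(gps$study_day), , drop = FALSE]
    lab <- label_states(gps, speed_threshold_kmh, gap_min)

    scr <- streams$screen[streams$screen$participant == p, , drop = FALSE]
    scr <- localize(scr, tzr)
    sess <- sessionize(scr)
    ema <- streams$ema[streams$ema$participant == p, , drop = FALSE]
    ema <- localize(ema, tzr)
    wear <- streams$wearable[streams$wearable$participant == p, ,
                             drop = FALSE]

    for (wi in seq_along(windows)) {
      wdays <- windows[[wi]]
      wlab <- lab[lab$study_day %in% wdays, , drop = FALSE]
      clus <- cluster_stationary(wlab, max_dist_m, k_max,
                                 seed = derive_seed(seed,
                                                    paste0(p, "-w", wi)))
      for (d in wdays) {
        if (d > study_days) next
        day_date <- enroll + (d - 1)
        mf <- if (any(wlab$study_day == d)) {
          extract_mobility_features(wlab, clus, window = d)
        } else NULL
        um <- daily_usage_features(sess, scr, day_date)
        wd <- wear[!is.na(wear$date) & wear$date == day_date, ,
                   drop = FALSE]
        wrec <- if (nrow(wd) == 1) validate_wearable(wd[1, ]) else NULL
        mood <- daily_mood(ema, day_date)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, study_day = d,
          total_distance = if (!is.null(mf)) mf$total_distance else NA,
          location_variance = if (!is.null(mf)) mf$location_variance else NA,
          entropy = if (!is.null(mf)) mf$entropy else NA,
          normalized_entropy = if (!is.null(mf)) mf$normalized_entropy else NA,
          homestay = if (!is.null(mf)) mf$homestay else NA,
          usage_duration = if (um$covered) um$usage_duration else NA,
          usage_frequency = if (um$covered) um$usage_frequency else NA,
          steps = if (!is.null(wrec)) wrec$steps else NA,
          met_avg = if (!is.null(wrec)) wrec$met_avg else NA,
          tst = if (!is.null(wrec)) wrec$tst else NA,
          sol = if (!is.null(wrec)) wrec$sol else NA,
          waso = if (!is.null(wrec)) wrec$waso else NA,
          tib = if (!is.null(wrec)) wrec$tib else NA,
          hrv_rmssd = if (!is.null(wrec)) wrec$hrv_rmssd else NA,
          valence = mood$valence_mean, arousal = mood$arousal_mean,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "ledger") <- ledger
  out
}

#' Assemble the standardized model table
#'
#' Pools daily features into the two assessment windows, scores the DASS-21
#' responses, pairs window 1 with T1 and window 2 with T2, and
#' z-standardizes predictors and outcomes over all observed rows.
#'
#' @param daily daily feature table from [extract_features()].
#' @param dass_responses DASS item table (`participant`,
#'   `assessment_point`, `item_1..21`).
#' @param min_coverage minimum defined days per window; default 5.
#' @return Standardized model table (see [standardize_model_table()]).
#' @export
build_model_table <- function(daily, dass_responses, min_coverage = 5) {
  pooled <- pool_windows(daily, min_coverage = min_coverage)
  scored <- score_dass_table(dass_responses)
  for (oc in c("depression", "anxiety", "stress")) pooled[[oc]] <- NA_real_
  for (i in seq_len(nrow(pooled))) {
    pt <- c("T1", "T2")[pooled$window[i]]
    row <- scored[scored$participant == pooled$participant[i] &
                    scored$assessment_point == pt, , drop = FALSE]
    if (nrow(row) == 1) {
      pooled$depression[i] <- row$depression
      pooled$anxiety[i] <- row$anxiety
      pooled$stress[i] <- row$stress
    }
  }
  standardize_model_table(pooled)
}

#' Run the full analysis stage
#'
#' Intraclass correlations, cluster-wise Spearman/Holm correlations,
#' multilevel multiple imputation and the single-predictor to combined
#' model ladder for each outcome.
#'
#' @param table standardized model table.
#' @param m,iterations,donors imputation settings (defaults 20 / 15 / 5).
#' @param seed root seed.
#' @param outcomes outcomes to model.
#' @return List of class `mobimood_analysis`: `icc`, `correlations`,
#'   `imputations`, `ladders` (one per outcome).
#' @export
analyze_cohort <- function(table, m = 20, iterations = 15, donors = 5,
                           seed = 1L,
                           outcomes = c("depression", "anxiety", "stress")) {
  iccs <- vapply(outcomes, function(oc) icc(table[[oc]],
                                            table$participant), 0)
  cors <- spearman_with_holm(table, outcomes = outcomes)
  imp <- impute_mpmm(table, m = m, iterations = iterations,
                     donors = donors,
                     seed = derive_seed(seed, "impute"))
  ladders <- lapply(outcomes, function(oc) build_model_ladder(imp, oc))
  names(ladders) <- outcomes
  structure(list(icc = iccs, correlations = cors, imputations = imp,
                 ladders = ladders), class = "mobimood_analysis")
}

#' @export
print.mobimood_analysis <- function(x, ...) {
  cat("Intraclass correlations:\n")
  print(round(x$icc, 3))
  cat("\nCluster-wise Holm-adjusted Spearman correlations (significant",
      "rows):\n")
  sig <- x$correlations[!is.na(x$correlations$p_adjusted) &
                          x$correlations$p_adjusted < 0.05, ]
  if (nrow(sig)) print(sig) else cat("(none below 0.05)\n")
  for (oc in names(x$ladders)) {
    cat("\n")
    print(x$ladders[[oc]])
  }
  invisible(x)
}

#' Run the pipeline end to end
#'
#' Stages: `simulate` (write a synthetic cohort to `dir/raw`), `extract`
#' (daily features + model table CSVs), `analyze` (correlations,
#' imputation, model ladders) and `report` (plain-text report in the
#' layout of the correlation and model-comparison tables). Each stage
#' reads only the previous stage's artifacts, so a missing upstream
#' artifact names the stage to rerun. A manifest (JSON) records the
#' configuration and seeds. Rerunning with the same root seed is
#' byte-identical.
#'
#' @param dir working directory for artifacts.
#' @param stages subset of `c("simulate", "extract", "analyze", "report")`.
#' @param config a [cohort_config()] (stage `simulate`).
#' @param m,iterations,donors imputation settings; defaults 20 / 15 / 5.
#' @param seed root seed for extract/analyze stages; default the config
#'   seed.
#' @return Invisible list of stage outputs.
#' @export
run_pipeline <- function(dir, stages = c("simulate", "extract", "analyze",
                                         "report"),
                         config = cohort_config(n_participants = 10,
                                                seed = 1L),
                         m = 20, iterations = 15, donors = 5,
                         seed = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- seed %||% config$seed
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  raw_dir <- file.path(dir, "raw")
  out <- list()
  need <- function(f, stage) {
    if (!file.exists(f)) {
      stop("missing artifact '", f, "': run the '", stage,
           "' stage first", call. = FALSE)
    }
  }
  if ("simulate" %in% stages) {
    cohort <- simulate_cohort(config)
    write_cohort(cohort, raw_dir)
    out$cohort <- cohort
    message("simulate: wrote ", nrow(cohort$gps), " GPS fixes for ",
            config$n_participants, " participants to ", raw_dir)
  }
  if ("extract" %in% stages) {
    need(file.path(raw_dir, "locations.csv"), "simulate")
    streams <- read_cohort(raw_dir)
    daily <- extract_features(streams, study_days = config$study_days,
                              seed = derive_seed(seed, "extract"))
    utils::write.csv(daily, file.path(dir, "daily_features.csv"),
                     row.names = FALSE)
    scored <- score_dass_table(streams$dass)
    utils::write.csv(scored, file.path(dir, "dass_scores.csv"),
                     row.names = FALSE)
    table <- build_model_table(daily, streams$dass)
    utils::write.csv(table, file.path(dir, "model_table.csv"),
                     row.names = FALSE)
    led <- attr(daily, "ledger")
    message("extract: ", nrow(daily), " participant-days; removals: ",
            paste(names(led), led, sep = "=", collapse = ", "))
    out$daily <- daily
    out$table <- table
  }
  if ("analyze" %in% stages) {
    f <- file.path(dir, "model_table.csv")
    need(f, "extract")
    table <- utils::read.csv(f, stringsAsFactors = FALSE)
    analysis <- analyze_cohort(table, m = m, iterations = iterations,
                               donors = donors,
                               seed = derive_seed(seed, "analyze"))
    utils::write.csv(analysis$correlations,
                     file.path(dir, "correlations.csv"),
                     row.names = FALSE)
    singles <- do.call(rbind, lapply(names(analysis$ladders), function(oc) {
      s <- analysis$ladders[[oc]]$single
      s$outcome <- oc
      s
    }))
    utils::write.csv(singles, file.path(dir, "single_predictor_models.csv"),
                     row.names = FALSE)
    stage_rows <- list()
    cmp_rows <- list()
    for (oc in names(analysis$ladders)) {
      lad <- analysis$ladders[[oc]]
      for (nm in names(lad$stages)) {
        st <- lad$stages[[nm]]
        if (is.null(st$pooled)) {
          stage_rows[[length(stage_rows) + 1L]] <- data.frame(
            outcome = oc, stage = nm, term = "(none identified)",
            estimate = NA, se = NA, df = NA, t = NA, p = NA)
        } else {
          cf <- st$pooled$coefficients
          stage_rows[[length(stage_rows) + 1L]] <- data.frame(
            outcome = oc, stage = nm, cf[c("term", "estimate", "se",
                                           "df", "t", "p")])
        }
      }
      if (nrow(lad$comparisons)) {
        cmp <- lad$comparisons
        cmp$outcome <- oc
        cmp_rows[[length(cmp_rows) + 1L]] <- cmp
      }
    }
    utils::write.csv(do.call(rbind, stage_rows),
                     file.path(dir, "model_ladders.csv"),
                     row.names = FALSE)
    if (length(cmp_rows)) {
      utils::write.csv(do.call(rbind, cmp_rows),
                       file.path(dir, "model_comparisons.csv"),
                       row.names = FALSE)
    }
    saveRDS_path <- file.path(dir, "analysis.rds")
    saveRDS(analysis, saveRDS_path)
    out$analysis <- analysis
    message("analyze: ICC ",
            paste(sprintf("%s=%.2f", names(analysis$icc), analysis$icc),
                  collapse = ", "))
  }
  if ("report" %in% stages) {
    f <- file.path(dir, "analysis.rds")
    need(f, "analyze")
    analysis <- readRDS(f)
    rp <- file.path(dir, "report.txt")
    con <- file(rp, "w")
    sink(con)
    on.exit({ sink(); close(con) }, add = TRUE)
    print(analysis)
    sink()
    close(con)
    on.exit(NULL)
    message("report: wrote ", rp)
    out$report <- rp
  }
  cfg_str <- paste(utils::capture.output(utils::str(unclass(config))),
                   collapse = "\n")
  manifest <- list(
    stages = stages,
    seed = seed,
    config_hash = sprintf("%08x", derive_seed(0, cfg_str)),
    config = unclass(config)[setdiff(names(unclass(config)),
                                     "planted_betas")],
    planted_betas = config$planted_betas,
    m = m, iterations = iterations, donors = donors,
    timestamp = NULL
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(out)
}
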