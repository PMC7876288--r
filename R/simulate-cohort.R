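# Full raw-stream cohort generator: GPS traces, screen events, wearable
# daily summaries, momentary mood and DASS-21 item responses, all driven by
# the same latent participant-window feature values that generate the
# outcomes, plus MAR masking of assessments and sensing days.

# distribute an integer subscore over 7 items rated 0-3 (largest-remainder
# with equal weights: only the sum matters downstream)
distribute_items <- function(score) {
  stopifnot(score >= 0, score <= 21)
  base <- score %/% 7
  rem <- score %% 7
  items <- rep(base, 7)
  if (rem > 0) items[seq_len(rem)] <- items[seq_len(rem)] + 1
  items
}

dass_scale_params <- list(depression = c(mu = 3.78, sd = 3.48),
                          anxiety = c(mu = 2.73, sd = 2.68),
                          stress = c(mu = 6.00, sd = 3.82))

#' Simulate a complete raw study cohort
#'
#' Generates, for every participant: a 30-day GPS trace (home plus up to
#' two secondary anchors, visit schedules shaped by the participant-window
#' latent mobility values), screen unlock/lock events matching the latent
#' usage frequency and duration, wearable daily summaries, three momentary
#' mood reports per day, and DASS-21 item responses at days 1 (T0), 16
#' (T1) and 31 (T2) whose subscale sums follow the planted outcome model.
#' Assessments are masked at `dass_missing_rate` and sensing days (GPS +
#' wearable) at `sensing_missing_rate`, both with logistic probabilities
#' driven by the observed usage-frequency covariate (MAR by construction;
#' the screen stream itself is never masked). Latent subscores falling
#' outside 0-21 are clipped and counted.
#'
#' @param config a [cohort_config()].
#' @param enrollment_date local date of study day 1; default
#'   `"2020-04-15"`.
#' @param tz IANA timezone for every participant; default
#'   `"Europe/Helsinki"`.
#' @return Object of class `cohort`: `gps`, `screen`, `wearable`, `ema`,
#'   `dass`, `timezones`, `enrollment` (data.frames keyed by
#'   `participant`), `truth` (planted parameters and latent window
#'   features), `clipped` (count of clipped subscores), `config`.
#' @export
simulate_cohort <- function(config, enrollment_date = "2020-04-15",
                            tz = "Europe/Helsinki") {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  nd <- config$study_days
  enroll <- as.Date(enrollment_date)
  start_ms <- as.numeric(as.POSIXct(paste(enroll, "00:00:00"),
                                    tz = tz)) * 1000
  # latent window features + outcomes, no table-level masking
  cfg0 <- config
  cfg0$dass_missing_rate <- 0
  cfg0$sensing_missing_rate <- 0
  sim <- simulate_model_table(cfg0, n_windows = 2)
  lat_tab <- sim$complete
  pids <- unique(lat_tab$participant)
  z <- function(p, w, f) lat_tab[lat_tab$participant == p &
                                   lat_tab$window == w, f]
  window_of <- function(day) if (day <= 15) 1 else 2

  gps_l <- list(); screen_l <- list(); wear_l <- list(); ema_l <- list()
  dass_l <- list(); clipped <- 0L

  # MAR intercepts for the two masking channels
  a_dass <- mar_intercept(config$dass_missing_rate, config$mar_slope)
  a_sens <- mar_intercept(config$sensing_missing_rate, config$mar_slope)

  for (pi in seq_along(pids)) {
    p <- pids[pi]
    pseed <- derive_seed(config$seed, paste0("participant-", pi))
    res <- with_seed(pseed, {
      # ---- GPS profile & schedule driven by latent mobility values
      home <- c(60.17 + stats::runif(1, -0.2, 0.2),
                24.94 + stats::runif(1, -0.4, 0.4))
      z_lv <- vapply(1:2, function(w) z(p, w, "location_variance"), 0)
      z_ent <- vapply(1:2, function(w) z(p, w, "entropy"), 0)
      z_home <- vapply(1:2, function(w) z(p, w, "homestay"), 0)
      z_dist <- vapply(1:2, function(w) z(p, w, "total_distance"), 0)
      work_km <- 1.2 * exp(0.35 * mean(z_lv))
      deg_lat <- 1 / 111.19493
      anchors <- data.frame(
        latitude = c(home[1], home[1] + 0.7 * deg_lat),
        longitude = c(home[2] + work_km * deg_lat / cos(home[1] * pi / 180),
                      home[2]))
      sched <- list()
      for (d in seq_len(nd)) {
        w <- window_of(d)
        if (stats::runif(1) < stats::plogis(0.9 + 0.6 * z_ent[w] +
                                              0.4 * z_dist[w])) {
          dur <- min(max(5 + 1.5 * z_ent[w] - 1.5 * z_home[w], 1), 9)
          sched[[length(sched) + 1L]] <- data.frame(
            day = d, anchor = 1, start_hour = 9, end_hour = 9 + dur)
        }
        if (stats::runif(1) < stats::plogis(-0.6 + 0.5 * z_dist[w])) {
          sched[[length(sched) + 1L]] <- data.frame(
            day = d, anchor = 2, start_hour = 19, end_hour = 19.7)
        }
      }
      sched <- if (length(sched)) do.call(rbind, sched) else NULL
      prof <- gps_profile(home, anchors = anchors, schedule = sched,
                          jitter_sd_m = 12)
      gps <- simulate_gps_trace(prof, days = seq_len(nd),
                                seed = derive_seed(pseed, "gps"),
                                start_ms = start_ms)
      attr(gps, "planted") <- NULL

      # ---- daily latent draws around the window values
      daily_z <- function(zw, sd = 0.3) {
        vapply(seq_len(nd), function(d) zw[window_of(d)] +
                 stats::rnorm(1, sd = sd), 0)
      }
      zf <- function(f) vapply(1:2, function(w) z(p, w, f), 0)
      zd_freq <- daily_z(zf("usage_frequency"))
      zd_dur <- daily_z(zf("usage_duration"))
      zd <- lapply(c(steps = "steps", met_avg = "met_avg", tst = "tst",
                     sol = "sol", waso = "waso", tib = "tib",
                     hrv_rmssd = "hrv_rmssd", valence = "valence",
                     arousal = "arousal"),
                   function(f) daily_z(zf(f)))

      # ---- screen events: k sessions/day in equal slots
      scr <- list()
      for (d in seq_len(nd)) {
        day0 <- start_ms + (d - 1) * 86400 * 1000
        k <- max(1L, stats::rpois(1, 35 * exp(0.25 * zd_freq[d])))
        total_min <- max(10, 150 + 40 * zd_dur[d])
        wgt <- stats::rgamma(k, 1.2)
        durs <- total_min * wgt / sum(wgt)
        slot <- 86400 / k
        st <- (seq_len(k) - 1) * slot + stats::runif(k, 30, 60)
        en <- pmin(st + durs * 60, (seq_len(k)) * slot - 30)
        en <- pmax(en, st + 10)
        scr[[d]] <- data.frame(
          timestamp = day0 + round(c(st, en) * 1000),
          status = rep(c("unlocked", "locked"), each = k))
      }
      screen <- do.call(rbind, scr)
      screen <- screen[order(screen$timestamp), ]

      # ---- wearable daily summaries
      tst <- pmax(180, 420 + 45 * zd$tst)
      sol <- pmax(1, 15 + 7 * zd$sol)
      waso <- pmax(0, 25 + 12 * zd$waso)
      tib_raw <- 480 + 45 * zd$tib
      tib <- pmax(tib_raw, tst + sol + waso + 5)
      wear <- data.frame(
        participant = p, date = enroll + (seq_len(nd) - 1),
        study_day = seq_len(nd),
        steps = round(pmax(0, 8000 + 2500 * zd$steps)),
        met_avg = pmax(0.9, 1.45 + 0.15 * zd$met_avg),
        tst = tst, sol = sol, waso = waso, tib = tib,
        hrv_rmssd = pmax(5, 55 + 15 * zd$hrv_rmssd))

      # ---- EMA: three prompts per day
      ema <- list()
      for (d in seq_len(nd)) {
        day0 <- start_ms + (d - 1) * 86400 * 1000
        hours <- c(10, 14, 20)
        val <- pmin(pmax(round(1.8 * zd$valence[d] +
                                 stats::rnorm(3, sd = 0.8)), -4), 4)
        aro <- pmin(pmax(round(1.8 * zd$arousal[d] +
                                 stats::rnorm(3, sd = 0.8)), -4), 4)
        ema[[d]] <- data.frame(timestamp = day0 + hours * 3600 * 1000,
                               valence = val, arousal = aro)
      }
      ema <- do.call(rbind, ema)

      # ---- DASS item responses at T0 / T1 / T2
      dass <- list()
      pts <- c("T0", "T1", "T2")
      for (ai in seq_along(config$assessment_days)) {
        pt <- pts[ai]
        row <- list(participant = p, assessment_point = pt,
                    day = config$assessment_days[ai])
        for (oc in names(dass_scale_params)) {
          y <- if (pt == "T0") {
            sim$truth$intercepts[[oc]][pi] + stats::rnorm(1, sd = 0.7)
          } else {
            z(p, ai - 1, oc)
          }
          pr <- dass_scale_params[[oc]]
          raw <- round(pr["mu"] + pr["sd"] * y)
          if (raw < 0 || raw > 21) clipped <- clipped + 1L
          sc <- min(max(raw, 0), 21)
          items <- distribute_items(sc)
          key <- dass_items()
          full <- integer(21)
          full[key$item[key$scale == oc]] <- items
          row[[oc]] <- full
        }
        it <- row$depression + row$anxiety + row$stress
        rec <- as.data.frame(c(list(participant = p,
                                    assessment_point = pt),
                               stats::setNames(as.list(it),
                                               paste0("item_", 1:21))),
                             stringsAsFactors = FALSE)
        dass[[ai]] <- rec
      }
      dass <- do.call(rbind, dass)

      # ---- MAR masking
      # assessments T1/T2 masked on the window usage-frequency latent
      zw_freq <- zf("usage_frequency")
      keep_dass <- rep(TRUE, nrow(dass))
      for (ai in 2:3) {
        pm <- stats::plogis(a_dass + config$mar_slope * zw_freq[ai - 1])
        if (stats::runif(1) < pm) keep_dass[ai] <- FALSE
      }
      dass <- dass[keep_dass, , drop = FALSE]
      # sensing days (GPS + wearable) masked on the daily usage driver
      pm_day <- stats::plogis(a_sens + config$mar_slope * zd_freq)
      drop_day <- stats::runif(nd) < pm_day
      if (any(drop_day)) {
        dropped <- which(drop_day)
        day_of <- floor((gps$timestamp - start_ms) / (86400 * 1000)) + 1
        gps <- gps[!(day_of %in% dropped), , drop = FALSE]
        wear <- wear[!(wear$study_day %in% dropped), , drop = FALSE]
      }
      gps$participant <- p
      screen$participant <- p
      ema$participant <- p
      list(gps = gps, screen = screen, wear = wear, ema = ema,
           dass = dass)
    })
    gps_l[[pi]] <- res$gps
    screen_l[[pi]] <- res$screen
    wear_l[[pi]] <- res$wear
    ema_l[[pi]] <- res$ema
    dass_l[[pi]] <- res$dass
  }

  structure(list(
    gps = do.call(rbind, gps_l),
    screen = do.call(rbind, screen_l),
    wearable = do.call(rbind, wear_l),
    ema = do.call(rbind, ema_l),
    dass = do.call(rbind, dass_l),
    timezones = data.frame(participant = pids,
                           timestamp = start_ms, timezone = tz,
                           stringsAsFactors = FALSE),
    enrollment = data.frame(participant = pids, date = enroll,
                            stringsAsFactors = FALSE),
    truth = c(sim$truth, list(latent_windows = lat_tab)),
    clipped = clipped,
    config = config
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", length(unique(x$enrollment$participant)),
      "participants,", x$config$study_days, "study days;",
      nrow(x$gps), "GPS fixes,", nrow(x$screen), "screen events,",
      nrow(x$dass), "DASS responses\n")
  if (x$clipped > 0) {
    cat("note:", x$clipped, "latent subscore(s) clipped into [0, 21]\n")
  }
  invisible(x)
}
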