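# Wearable daily summaries (activity, sleep, HRV) and momentary mood.

#' Validate a wearable daily summary record
#'
#' Range checks for the consumed daily outputs: steps, 24-h MET average,
#' total sleep time (TST), sleep onset latency (SOL), wake after sleep
#' onset (WASO), time in bed (TIB, all minutes) and nightly RMSSD (ms).
#' Invariants: all non-negative; `tst <= tib`; `sol + waso <= tib - tst +
#' 30` (30 min tolerance); `hrv_rmssd <= 500`. Violating fields are set to
#' NA and listed in `flags`; validation never raises.
#'
#' @param record one-row data.frame or named list with fields `date`,
#'   `steps`, `met_avg`, `tst`, `sol`, `waso`, `tib`, `hrv_rmssd`.
#' @return The record (as a one-row data.frame) with offending fields NA,
#'   plus a `flags` attribute naming each violated invariant.
#' @export
validate_wearable <- function(record) {
  rec <- as.data.frame(record, stringsAsFactors = FALSE)
  flags <- character(0)
  num_fields <- c("steps", "met_avg", "tst", "sol", "waso", "tib",
                  "hrv_rmssd")
  for (f in num_fields) {
    if (!is.null(rec[[f]]) && !is.na(rec[[f]]) && rec[[f]] < 0) {
      flags <- c(flags, paste0(f, ":negative"))
      rec[[f]] <- NA_real_
    }
  }
  if (!is.na(rec$tst) && !is.na(rec$tib) && rec$tst > rec$tib) {
    flags <- c(flags, "tst:exceeds_tib")
    rec$tst <- NA_real_
  }
  if (!anyNA(rec[c("sol", "waso", "tst", "tib")]) &&
      rec$sol + rec$waso > rec$tib - rec$tst + 30) {
    flags <- c(flags, "sol_waso:inconsistent_with_tib")
    rec$sol <- NA_real_
    rec$waso <- NA_real_
  }
  if (!is.na(rec$hrv_rmssd) && rec$hrv_rmssd > 500) {
    flags <- c(flags, "hrv_rmssd:implausible")
    rec$hrv_rmssd <- NA_real_
  }
  attr(rec, "flags") <- flags
  rec
}

#' Daily mood from momentary reports
#'
#' Unweighted arithmetic mean of the valence and arousal ratings (9-point
#' integer scales, -4..4) reported on a day; undefined (NA) when the day
#' has no reports. Untouched default-zero responses are retained unless
#' `drop_default_zero` is set.
#'
#' @param responses data.frame with `valence`, `arousal` (integers -4..4)
#'   and `local_date`.
#' @param day a `Date`.
#' @param drop_default_zero drop responses with valence and arousal both
#'   exactly 0 (possible untouched defaults); default FALSE.
#' @return list with `valence_mean`, `arousal_mean`, `n_responses`.
#' @export
daily_mood <- function(responses, day, drop_default_zero = FALSE) {
  stopifnot(all(is.na(responses$valence) | (responses$valence %in% -4:4)),
            all(is.na(responses$arousal) | (responses$arousal %in% -4:4)))
  r <- responses[responses$local_date == day, , drop = FALSE]
  if (drop_default_zero) {
    r <- r[!(r$valence == 0 & r$arousal == 0), , drop = FALSE]
  }
  if (nrow(r) == 0) {
    return(list(valence_mean = NA_real_, arousal_mean = NA_real_,
                n_responses = 0L))
  }
  list(valence_mean = mean(r$valence, na.rm = TRUE),
       arousal_mean = mean(r$arousal, na.rm = TRUE),
       n_responses = nrow(r))
}
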