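# Shared fixture builders. All fixtures are generated in code; coordinates
# sit around Helsinki so timezone fixtures are realistic.

utc_records <- function() data.frame(timestamp = 0, timezone = "UTC")

# a bare GPS sample table
gps_df <- function(timestamp, latitude, longitude, accuracy = 10) {
  data.frame(timestamp = timestamp, latitude = latitude,
             longitude = longitude, accuracy = accuracy)
}

# move `km` kilometers north of (lat, lon)
north_of <- function(lat, km) lat + km / 111.19493

# a localized, labeled stationary trace alternating dwell among anchors:
# `dwell_sec` per anchor visit, sampled every `step` seconds
anchor_trace <- function(anchors, dwell_per_anchor_sec, step = 60,
                         start_ms = 0) {
  rows <- list()
  t <- start_ms
  for (i in seq_len(nrow(anchors))) {
    nsteps <- dwell_per_anchor_sec[i] / step
    for (s in seq_len(nsteps)) {
      rows[[length(rows) + 1L]] <- gps_df(t, anchors$latitude[i],
                                          anchors$longitude[i])
      t <- t + step * 1000
    }
  }
  do.call(rbind, rows)
}

# brute-force Holm step-down: sort, multiply by (k - rank + 1), enforce
# monotonicity and the cap at 1
holm_brute <- function(p) {
  k <- length(p)
  o <- order(p)
  adj <- pmin(p[o] * (k - seq_len(k) + 1), 1)
  adj <- cummax(adj)
  out <- numeric(k)
  out[o] <- adj
  out
}

# full prep chain on a raw sample table: localize (UTC), clean, label
prep_trace <- function(samples, accuracy_cut = Inf, study_day = 1L) {
  tr <- localize(samples, utc_records())
  tr <- clean_trace(tr, accuracy_cut)
  tr$study_day <- study_day
  label_states(tr)
}
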