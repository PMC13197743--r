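# Shared fixtures, built in code.

constant_signal <- function(value = 95, hours = 1) {
  spo2_signal(rep(value, round(hours * 3600)), rate_hz = 1,
              subject_id = "const")
}

# Flat baseline with one symmetric triangular dip: linear fall at
# `slope` %/s from `baseline` to `baseline - depth` and mirror
# recovery. Returns the signal plus the construction parameters.
triangle_dip_signal <- function(baseline = 96, depth = 10, slope = 0.5,
                                nadir_at = 300, total = 600) {
  half <- depth / slope
  t <- seq_len(total) - 1
  v <- baseline - pmax(0, depth - slope * abs(t - nadir_at))
  list(signal = spo2_signal(v, rate_hz = 1, subject_id = "tri"),
       baseline = baseline, depth = depth, half = half,
       nadir_idx = nadir_at + 1)
}

# Brute-force extremum scan: index-by-index, an extremum is the first
# sample of a (possibly plateau) run that the signal enters from one
# side and leaves on the other. Deliberately dumb and quadratic.
oracle_extrema <- function(v, kind = c("min", "max")) {
  kind <- match.arg(kind)
  n <- length(v)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (v[i] == v[i - 1]) next  # not the first sample of its run
    j <- i + 1
    while (j <= n && v[j] == v[i]) j <- j + 1
    if (j > n) next
    hit <- if (kind == "min") v[i - 1] > v[i] && v[j] > v[i]
           else v[i - 1] < v[i] && v[j] < v[i]
    if (hit) out <- c(out, i)
  }
  out
}

# Brute-force valley filter: prominence against the nearest preceding
# local maximum (falling back to the prefix maximum) >= min_depth.
oracle_valleys <- function(v, min_depth = 2) {
  minima <- oracle_extrema(v, "min")
  maxima <- oracle_extrema(v, "max")
  keep <- vapply(minima, function(i) {
    prev_max <- maxima[maxima < i]
    pk <- if (length(prev_max)) v[prev_max[length(prev_max)]]
          else max(v[seq_len(i - 1)])
    pk - v[i] >= min_depth
  }, logical(1))
  minima[keep]
}

# Independent trapezoid integration of the baseline deficit over each
# delineated window (dual route for the HB oracle checks).
oracle_event_areas <- function(signal, events) {
  ev <- events$events
  vapply(seq_len(nrow(ev)), function(i) {
    idx <- ev$win_start[i]:ev$win_finish[i]
    d <- pmax(0, ev$baseline[i] - signal$values[idx])
    d[!signal$valid_mask[idx]] <- 0
    a <- 0
    for (k in seq_len(length(d) - 1)) a <- a + (d[k] + d[k + 1]) / 2
    a
  }, numeric(1))
}

# All-pairs concordance AUC with half-credit ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Write a minimal one-channel EDF file (int16 little-endian).
write_mini_edf <- function(path, values, rate_hz, label = "SpO2") {
  rec_dur <- 1
  n_per_rec <- rate_hz * rec_dur
  n_rec <- length(values) / n_per_rec
  stopifnot(n_rec == round(n_rec))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(pad("0", 8), pad("X", 80), pad("X", 80),
                   pad("01.01.24", 8), pad("00.00.00", 8),
                   pad(256 + 256, 8), pad("", 44), pad(n_rec, 8),
                   pad(rec_dur, 8), pad(1, 4)),
            con, eos = NULL)
  writeChar(paste0(pad(label, 16), pad("pulse oximeter", 80),
                   pad("%", 8), pad(0, 8), pad(100, 8), pad(-32768, 8),
                   pad(32767, 8), pad("", 80), pad(n_per_rec, 8),
                   pad("", 32)),
            con, eos = NULL)
  digital <- as.integer(round(values / 100 * 65535 - 32768))
  writeBin(digital, con, size = 2, endian = "little")
  invisible(path)
}

strong_profiles <- function(duration_h = 2) {
  list(osa = signal_profile(event_rate_per_h = 30, depth_mean = 8,
                            depth_sd = 1, duration_mean = 30,
                            duration_sd = 5, noise_sd = 0.3,
                            duration_h = duration_h),
       non_osa = signal_profile(event_rate_per_h = 1, depth_mean = 5,
                                depth_sd = 0.5, duration_mean = 25,
                                duration_sd = 5, noise_sd = 0.3,
                                duration_h = duration_h))
}
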