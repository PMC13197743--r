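#' Mean and minimum saturation
#'
#' @param signal an [spo2_signal()]; at least one valid sample.
#' @return named numeric vector `c(mean_spo2, min_spo2)` over valid
#'   samples only.
#' @export
basic_stats <- function(signal) {
  v <- signal$values[signal$valid_mask]
  if (!length(v)) stop("degenerate input: no valid samples", call. = FALSE)
  c(mean_spo2 = mean(v), min_spo2 = min(v))
}

#' Time and fraction of sleep below a saturation threshold
#'
#' T90 counts valid 1 Hz samples strictly below `threshold` (so a
#' sample sitting exactly at 90% does not count) and reports minutes;
#' ST90 is that time as a percentage of total sleep time.
#'
#' @param signal an [spo2_signal()] at 1 Hz.
#' @param threshold percent, default 90.
#' @param tst_minutes total sleep time in minutes (> 0).
#' @return named vector `c(t90, st90)`, minutes and percent.
#' @export
time_below_threshold <- function(signal, threshold = 90, tst_minutes) {
  stopifnot(inherits(signal, "spo2_signal"), signal$rate_hz == 1)
  if (!is.numeric(tst_minutes) || tst_minutes <= 0) {
    stop("total sleep time must be positive", call. = FALSE)
  }
  t90 <- sum(signal$valid_mask & signal$values < threshold) / 60
  c(t90 = t90, st90 = 100 * t90 / tst_minutes)
}

entropy_nats <- function(intervals) {
  if (length(intervals) < 1L) return(0)
  p <- tabulate(factor(round(intervals)))
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Attention entropy of the saturation waveform
#'
#' Local maxima and minima of the trace (invalid samples removed, time
#' kept in seconds) define four interval streams between adjacent key
#' extrema: max-to-max, min-to-min, max-to-next-min, and
#' min-to-next-max. Each stream's intervals, binned at the native
#' 1-second resolution, give an empirical distribution whose Shannon
#' entropy (natural log) is computed; the reported value is the mean of
#' the four stream entropies. A perfectly periodic sawtooth therefore
#' scores 0, and irregular, fragmented desaturation patterns score
#' higher. Streams with fewer than two extrema contribute 0.
#'
#' @param signal an [spo2_signal()] at 1 Hz.
#' @return entropy in nats (>= 0).
#' @export
attention_entropy <- function(signal) {
  stopifnot(inherits(signal, "spo2_signal"))
  idx <- which(signal$valid_mask)
  v <- signal$values[idx]
  ex <- local_extrema(v)
  if (length(ex$minima) + length(ex$maxima) < 2L) return(0)
  max_t <- idx[ex$maxima]
  min_t <- idx[ex$minima]
  merged <- rbind(data.frame(t = max_t, type = "max"),
                  data.frame(t = min_t, type = "min"))
  merged <- merged[order(merged$t), ]
  nxt <- merged[-1, ]
  cur <- merged[-nrow(merged), ]
  mn <- nxt$t[cur$type == "max" & nxt$type == "min"] -
    cur$t[cur$type == "max" & nxt$type == "min"]
  nm <- nxt$t[cur$type == "min" & nxt$type == "max"] -
    cur$t[cur$type == "min" & nxt$type == "max"]
  mean(c(entropy_nats(diff(max_t)), entropy_nats(diff(min_t)),
         entropy_nats(mn), entropy_nats(nm)))
}

#' Lomb-Scargle periodogram of a masked signal
#'
#' Classic Lomb-Scargle power of the mean-removed valid samples,
#' evaluated on an arbitrary frequency grid; masked gaps are handled
#' natively since the estimator needs no uniform sampling. Power at a
#' frequency equals half the residual-sum-of-squares reduction of a
#' least-squares sinusoid fit at that frequency.
#'
#' @param signal an [spo2_signal()].
#' @param freqs frequencies, Hz (all > 0).
#' @return numeric vector of periodogram power (same length as
#'   `freqs`).
#' @export
lomb_scargle <- function(signal, freqs) {
  t <- (which(signal$valid_mask) - 1) / signal$rate_hz
  y <- signal$values[signal$valid_mask]
  y <- y - mean(y)
  lomb_power(t, y, freqs)
}

#' Ultradian-band spectral power
#'
#' Integrates the Lomb-Scargle periodogram over the ultradian band
#' (default 0.014-0.035 Hz, i.e. 30-70 s oscillation periods typical
#' of repetitive OSA desaturation cycles) and reports decibels,
#' `10 log10(P + 1e-12)`; the floor keeps constant signals finite at
#' -120 dB. Absolute dB levels are implementation- and
#' device-dependent; comparisons should use in-band fractions.
#'
#' @param signal an [spo2_signal()] with >= 10 min of valid samples.
#' @param band frequency interval, Hz.
#' @param n_freq grid points across the band (>= 200).
#' @return band power in dB.
#' @export
total_power <- function(signal, band = c(0.014, 0.035), n_freq = 256) {
  stopifnot(inherits(signal, "spo2_signal"))
  if (sum(signal$valid_mask) / signal$rate_hz < 600) {
    stop("degenerate input: need at least 10 minutes of valid signal",
         call. = FALSE)
  }
  n_freq <- max(200L, n_freq)
  freqs <- seq(band[1], band[2], length.out = n_freq)
  p <- lomb_scargle(signal, freqs)
  bp <- sum((p[-1] + p[-n_freq]) / 2 * diff(freqs))
  10 * log10(bp + 1e-12)
}

#' Canonical feature-name order
#' @return character vector of the eight oximetry parameter names.
#' @export
oximetry_feature_names <- function() {
  c("MeanSpO2", "MinSpO2", "ODI", "T90", "ST90", "HB", "AttnEn",
    "TotalPower")
}

#' Assemble the eight-parameter oximetry feature vector
#'
#' @param signal an [spo2_signal()] at 1 Hz.
#' @param events an `event_set` from [detect_events()] on this signal.
#' @param tst_hours total sleep time, hours; defaults to TRT (no
#'   staging, as in home sleep apnea testing).
#' @param trt_hours total recording time, hours; defaults to the
#'   signal length.
#' @return named numeric vector in the fixed order given by
#'   [oximetry_feature_names()].
#' @export
feature_vector <- function(signal, events = detect_events(signal),
                           tst_hours = trt_hours, trt_hours = NULL) {
  if (is.null(trt_hours)) trt_hours <- trt_hours(signal)
  bs <- basic_stats(signal)
  tb <- time_below_threshold(signal, 90, tst_minutes = tst_hours * 60)
  out <- c(bs[["mean_spo2"]], bs[["min_spo2"]],
           odi(events, tst_hours),
           tb[["t90"]], tb[["st90"]],
           hypoxic_burden(events, trt_hours),
           attention_entropy(signal),
           total_power(signal))
  names(out) <- oximetry_feature_names()
  out
}

#' Extract features for a whole cohort
#'
#' @param cohort_obj result of [generate_cohort()], or a list with
#'   `subjects` and `signals` in the same shape.
#' @param min_depth valley-candidacy prominence passed to
#'   [detect_events()].
#' @return the `subjects` data.frame with the eight feature columns
#'   appended.
#' @export
extract_cohort_features <- function(cohort_obj, min_depth = 2) {
  feats <- t(vapply(cohort_obj$signals, function(sig) {
    feature_vector(sig, detect_events(sig, min_depth))
  }, numeric(8)))
  cbind(cohort_obj$subjects, as.data.frame(feats))
}
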