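#' Construct an SpO2 signal object
#'
#' The canonical container for a nocturnal saturation trace: a numeric
#' vector of SpO2 values (%), a sampling rate in Hz, and a per-sample
#' validity mask. Samples outside the physiologically plausible range
#' (below 40% or above 100%) and non-finite samples are flagged invalid
#' automatically; their raw values are retained for inspection.
#'
#' Time is sample-indexed and 0-based: sample `k` covers the half-open
#' interval `[k/rate, (k+1)/rate)` seconds.
#'
#' @param values numeric vector of saturation percentages.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param valid_mask optional logical vector, same length as `values`;
#'   samples flagged `FALSE` are excluded from every computation.
#'   Plausibility flags are applied on top of a user-supplied mask.
#' @param subject_id opaque identifier carried through exports.
#' @return an object of class `spo2_signal` with fields `values`,
#'   `rate_hz`, `valid_mask`, `subject_id`.
#' @export
spo2_signal <- function(values, rate_hz = 1, valid_mask = NULL,
                        subject_id = NA_character_) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop("degenerate input: empty SpO2 record", call. = FALSE)
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("rate_hz must be a single positive number", call. = FALSE)
  }
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, length(values))
  stopifnot(is.logical(valid_mask), length(valid_mask) == length(values))
  plausible <- is.finite(values) & values >= 40 & values <= 100
  valid_mask <- valid_mask & plausible
  structure(
    list(values = values, rate_hz = rate_hz, valid_mask = valid_mask,
         subject_id = as.character(subject_id)),
    class = "spo2_signal"
  )
}

#' @export
print.spo2_signal <- function(x, ...) {
  cat(sprintf(
    "<spo2_signal> subject=%s  n=%d @ %g Hz  (%.2f h, %.1f%% valid)\n",
    x$subject_id, length(x$values), x$rate_hz,
    trt_hours(x), 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Total recording time
#'
#' @param signal an [spo2_signal()].
#' @return TRT in seconds (`trt_seconds`) or hours (`trt_hours`).
#' @export
trt_seconds <- function(signal) length(signal$values) / signal$rate_hz

#' @rdname trt_seconds
#' @export
trt_hours <- function(signal) trt_seconds(signal) / 3600

#' Read an SpO2 recording from disk
#'
#' Dispatches on `format`: `"delimited"` for two-column (time_s, spo2)
#' text with an optional header and auto-detected comma/tab separator,
#' or `"edf"` for European Data Format recordings, selecting the
#' saturation channel by `channel_hint` or a default name list.
#' Non-numeric or implausible samples are kept but masked invalid.
#'
#' @param path file path.
#' @param format `"delimited"` (default, also used for `.csv`/`.tsv`)
#'   or `"edf"`.
#' @param channel_hint optional channel-label pattern for EDF files.
#' @param subject_id identifier; defaults to the file stem.
#' @return an [spo2_signal()] at the file's native rate.
#' @export
read_signal <- function(path, format = c("delimited", "edf"),
                        channel_hint = NULL, subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file",
                               call. = FALSE)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "edf") {
    return(read_edf_spo2(path, channel_hint = channel_hint,
                         subject_id = subject_id))
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("degenerate input: empty file", call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- {
    fields <- strsplit(first, sep, fixed = TRUE)[[1]]
    any(is.na(suppressWarnings(as.numeric(fields))))
  }
  tab <- utils::read.table(path, sep = sep, header = has_header,
                           colClasses = "character",
                           blank.lines.skip = TRUE)
  if (ncol(tab) < 2L) stop("expected two columns (time_s, spo2)",
                           call. = FALSE)
  if (nrow(tab) == 0L) stop("degenerate input: empty record", call. = FALSE)
  time_s <- suppressWarnings(as.numeric(tab[[1]]))
  vals <- suppressWarnings(as.numeric(tab[[2]]))
  mask <- !is.na(vals)
  vals[is.na(vals)] <- NA_real_
  # native rate from the median time step; single-sample files default 1 Hz
  rate <- 1
  if (sum(!is.na(time_s)) >= 2L) {
    dt <- stats::median(diff(time_s[!is.na(time_s)]))
    if (is.finite(dt) && dt > 0) rate <- 1 / dt
  }
  spo2_signal(vals, rate_hz = rate, valid_mask = mask,
              subject_id = subject_id)
}

#' Write a signal in the canonical delimited-text exchange format
#'
#' @param signal an [spo2_signal()].
#' @param path output path; two comma-separated columns `time_s,spo2`
#'   with a header; invalid samples are written as `NA`.
#' @export
write_signal <- function(signal, path) {
  vals <- signal$values
  vals[!signal$valid_mask] <- NA_real_
  df <- data.frame(time_s = (seq_along(vals) - 1) / signal$rate_hz,
                   spo2 = vals)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

# Minimal EDF reader: 256-byte fixed header, per-signal headers, int16
# little-endian data records scaled digital -> physical. Only the
# saturation channel is materialized.
read_edf_spo2 <- function(path, channel_hint = NULL,
                          subject_id = NA_character_,
                          default_channels = c("SpO2", "SaO2", "OSAT",
                                               "Oxygen")) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) {
    stop("unreadable EDF: truncated header", call. = FALSE)
  }
  n_records <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF: no signals", call. = FALSE)
  field <- function(width) {
    vapply(seq_len(ns), function(i) {
      trimws(readChar(con, width, useBytes = TRUE))
    }, character(1))
  }
  labels <- field(16)
  field(80)  # transducer
  field(8)   # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)  # prefiltering
  n_samp <- as.integer(field(8))
  field(32)  # reserved
  patterns <- if (is.null(channel_hint)) default_channels else channel_hint
  ch <- NA_integer_
  for (p in patterns) {
    hit <- grep(p, labels, ignore.case = TRUE)
    if (length(hit)) { ch <- hit[1]; break }
  }
  if (is.na(ch)) {
    stop("no saturation channel found (labels: ",
         paste(labels, collapse = ", "), ")", call. = FALSE)
  }
  if (is.na(n_records) || n_records < 1L) {
    stop("degenerate input: EDF holds no data records", call. = FALSE)
  }
  gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
  out <- numeric(n_records * n_samp[ch])
  pos <- 0L
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = n_samp[s], size = 2,
                     signed = TRUE, endian = "little")
      if (s == ch) {
        out[pos + seq_len(n_samp[s])] <-
          phys_min[ch] + gain * (raw - dig_min[ch])
        pos <- pos + n_samp[s]
      }
    }
  }
  spo2_signal(out, rate_hz = n_samp[ch] / rec_dur, subject_id = subject_id)
}

#' Downsample a signal to the canonical 1 Hz grid
#'
#' Each output sample is the arithmetic mean of the valid native samples
#' in its 1-second half-open window `[k, k+1)`; windows containing no
#' valid sample are masked invalid. A 1 Hz input is returned unchanged.
#'
#' @param signal an [spo2_signal()] at any rate >= 1 Hz.
#' @return an [spo2_signal()] at 1 Hz.
#' @export
resample_to_1hz <- function(signal) {
  if (signal$rate_hz == 1) return(signal)
  if (signal$rate_hz < 1) {
    stop("cannot resample a rate below 1 Hz onto the 1 s grid",
         call. = FALSE)
  }
  n <- length(signal$values)
  # second index of each native sample (works for non-integer rates too)
  sec <- floor((seq_len(n) - 1) / signal$rate_hz)
  n_out <- floor(n / signal$rate_hz)
  sec <- sec + 1L  # 1-based bins
  keep <- signal$valid_mask & sec <= n_out
  sums <- numeric(n_out)
  cnts <- numeric(n_out)
  if (any(keep)) {
    agg <- rowsum(signal$values[keep], group = sec[keep])
    cnt <- rowsum(rep(1, sum(keep)), group = sec[keep])
    idx <- as.integer(rownames(agg))
    sums[idx] <- agg[, 1]
    cnts[idx] <- cnt[, 1]
  }
  vals <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
  spo2_signal(vals, rate_hz = 1, valid_mask = cnts > 0,
              subject_id = signal$subject_id)
}

#' Check the analyzable-duration requirement
#'
#' A recording is analyzable when it carries strictly more than
#' `required_hours` of valid 1 Hz samples (default 4 h).
#'
#' @param signal an [spo2_signal()] at 1 Hz.
#' @param required_hours required analyzable duration, hours.
#' @return a list of class `validity_report`: `analyzable_seconds`,
#'   `required_seconds`, `is_valid`, `invalid_fraction`.
#' @export
validate_recording <- function(signal, required_hours = 4) {
  stopifnot(inherits(signal, "spo2_signal"))
  if (signal$rate_hz != 1) signal <- resample_to_1hz(signal)
  analyzable <- sum(signal$valid_mask)
  required <- required_hours * 3600
  structure(
    list(analyzable_seconds = analyzable,
         required_seconds = required,
         is_valid = analyzable > required,
         invalid_fraction = 1 - analyzable / length(signal$values)),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> %.2f h analyzable (need > %.2f h): %s\n",
              x$analyzable_seconds / 3600, x$required_seconds / 3600,
              if (x$is_valid) "valid" else "INVALID"))
  invisible(x)
}
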