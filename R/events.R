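# Local extrema of a numeric run. Plateau runs collapse to their first
# index. Returns 1-based indices relative to the run.
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(list(minima = integer(0), maxima = integer(0)))
  s <- sign(diff(v))
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(minima = integer(0), maxima = integer(0)))
  sv <- s[nz]
  turn <- which(sv[-1] != sv[-length(sv)])
  idx <- nz[turn] + 1L  # first sample of each (possibly plateau) extremum
  list(minima = idx[sv[turn] < 0], maxima = idx[sv[turn] > 0])
}

# Maximal runs of valid samples as (start, end) index pairs.
valid_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = unname(starts[keep]), end = unname(ends[keep]))
}

#' Detect desaturation nadirs
#'
#' Finds local minima of the 1 Hz trace whose prominence relative to
#' the nearest preceding local maximum is at least `min_depth` percent.
#' Plateau minima collapse to the plateau's first sample; invalid
#' samples break extremal runs, so no valley spans a masked gap.
#'
#' The 2% default admits sub-threshold desaturations into the hypoxic
#' burden while keeping oximeter noise out; the 4% ODI rule is applied
#' downstream on event depth, not here.
#'
#' @param signal an [spo2_signal()] at 1 Hz.
#' @param min_depth minimum prominence, percent (default 2).
#' @return integer vector of nadir sample indices (1-based), ordered.
#' @export
detect_valleys <- function(signal, min_depth = 2) {
  stopifnot(inherits(signal, "spo2_signal"), signal$rate_hz == 1)
  out <- integer(0)
  runs <- valid_runs(signal$valid_mask)
  if (is.null(dim(runs)) || nrow(runs) == 0L) return(out)
  for (r in seq_len(nrow(runs))) {
    lo <- runs[[r, 1]]; hi <- runs[[r, 2]]
    v <- signal$values[lo:hi]
    ex <- local_extrema(v)
    if (!length(ex$minima)) next
    cm <- cummax(v)
    pm <- findInterval(ex$minima - 0.5, ex$maxima)
    peak_val <- ifelse(pm > 0, v[ex$maxima[pmax(pm, 1L)]],
                       cm[pmax(ex$minima - 1L, 1L)])
    keep <- peak_val - v[ex$minima] >= min_depth
    out <- c(out, lo + ex$minima[keep] - 1L)
  }
  sort(out)
}

#' Delineate desaturation events around detected nadirs
#'
#' For each nadir the event window is grown bidirectionally to the
#' nearest samples recovering at least 75% of the preceding
#' peak-to-nadir amplitude, clipped at recording (and valid-run) edges
#' and at midpoints between adjacent nadirs so windows stay pairwise
#' disjoint. After a first pass, windows longer than twice the
#' pass-one mean event duration are clipped symmetrically about their
#' nadir to that cap. The event baseline is the maximum SpO2 in the
#' 100 s preceding the window start (falling back to the preceding
#' peak when no prefix exists), and the event area is the trapezoidal
#' integral of the baseline deficit `max(0, baseline - SpO2)` across
#' the window.
#'
#' Nadirs belong to the same event when the signal never recovers to
#' the 75% level between them; such runs are merged onto their deepest
#' nadir before windows are delineated, so one physiological
#' desaturation is never split by noise wiggles on its flanks.
#'
#' @param signal an [spo2_signal()] at 1 Hz.
#' @param nadirs nadir indices from [detect_valleys()] on this signal.
#' @return an object of class `event_set`: `events` (data.frame with
#'   nadir_idx, preceding_peak_idx, win_start, win_finish, baseline,
#'   depth, duration_s, area) and `mean_duration_s`.
#' @export
delineate_events <- function(signal, nadirs) {
  stopifnot(inherits(signal, "spo2_signal"), signal$rate_hz == 1)
  n <- length(signal$values)
  if (any(nadirs < 1L | nadirs > n)) {
    stop("nadir index out of range", call. = FALSE)
  }
  nadirs <- sort(unique(as.integer(nadirs)))
  empty <- data.frame(nadir_idx = integer(0), preceding_peak_idx = integer(0),
                      win_start = integer(0), win_finish = integer(0),
                      baseline = numeric(0), depth = numeric(0),
                      duration_s = numeric(0), area = numeric(0))
  if (length(nadirs) == 0L) {
    return(structure(list(events = empty, mean_duration_s = 0),
                     class = "event_set"))
  }
  runs <- valid_runs(signal$valid_mask)
  v <- signal$values
  # per-run extrema, computed once (global sample indices)
  run_extrema <- lapply(seq_len(nrow(runs)), function(r) {
    lo <- runs[[r, 1]]
    ex <- local_extrema(v[lo:runs[[r, 2]]])
    list(minima = lo + ex$minima - 1L, maxima = lo + ex$maxima - 1L)
  })
  run_of <- function(i) {
    r <- which(runs[, 1] <= i & runs[, 2] >= i)
    if (!length(r)) stop("nadir lies on an invalid sample", call. = FALSE)
    r[1]
  }
  recovery_info <- function(ni) {
    r <- run_of(ni)
    lo <- runs[[r, 1]]; hi <- runs[[r, 2]]
    maxima <- run_extrema[[r]]$maxima
    prev_max <- maxima[maxima < ni]
    pk <- if (length(prev_max)) prev_max[length(prev_max)]
          else if (ni > lo) lo - 1L + which.max(v[lo:(ni - 1L)]) else ni
    recov <- v[ni] + 0.75 * (v[pk] - v[ni])
    right <- if (ni < hi) which(v[(ni + 1L):hi] >= recov) else integer(0)
    list(pk = pk, recov = recov, lo = lo, hi = hi,
         f_raw = if (length(right)) ni + right[1] else hi)
  }
  # merge nadirs not separated by a 75% recovery onto the deepest one
  if (length(nadirs) > 1L) {
    merged <- integer(0)
    cur <- nadirs[1]
    f_cur <- recovery_info(cur)$f_raw
    for (ni in nadirs[-1]) {
      if (ni < f_cur) {
        if (v[ni] < v[cur]) cur <- ni
        f_cur <- max(f_cur, recovery_info(cur)$f_raw)
      } else {
        merged <- c(merged, cur)
        cur <- ni
        f_cur <- recovery_info(cur)$f_raw
      }
    }
    nadirs <- c(merged, cur)
  }
  k <- length(nadirs)
  s0 <- integer(k); f0 <- integer(k); pk <- integer(k)
  for (i in seq_len(k)) {
    ni <- nadirs[i]
    ri <- recovery_info(ni)
    pk[i] <- ri$pk
    left <- which(v[ri$lo:ni] >= ri$recov)
    s <- if (length(left)) ri$lo + left[length(left)] - 1L else ri$lo
    f <- ri$f_raw
    # disjointness: clip at midpoints between adjacent nadirs
    if (i > 1L) s <- max(s, (nadirs[i - 1L] + ni) %/% 2L)
    if (i < k) f <- min(f, (ni + nadirs[i + 1L]) %/% 2L)
    s0[i] <- min(s, ni); f0[i] <- max(f, ni + 1L)
  }
  # pass-two refinement: cap over-long windows at 2x the mean duration
  mean_dur <- mean(f0 - s0)
  cap <- 2 * mean_dur
  for (i in seq_len(k)) {
    if (f0[i] - s0[i] > cap) {
      half <- floor(cap / 2)
      s0[i] <- max(s0[i], nadirs[i] - as.integer(half))
      f0[i] <- min(f0[i], s0[i] + as.integer(ceiling(cap)))
      if (f0[i] <= nadirs[i]) f0[i] <- nadirs[i] + 1L
    }
  }
  baseline <- numeric(k); depth <- numeric(k); area <- numeric(k)
  for (i in seq_len(k)) {
    pre <- max(1L, s0[i] - 100L):(s0[i] - 1L)
    if (s0[i] == 1L) pre <- integer(0)
    pre <- pre[pre >= 1L & signal$valid_mask[pre]]
    baseline[i] <- if (length(pre)) max(v[pre]) else v[pk[i]]
    idx <- s0[i]:f0[i]
    d <- pmax(0, baseline[i] - v[idx])
    d[!signal$valid_mask[idx]] <- 0
    # depth = maximal in-window deficit; equals baseline - nadir value
    # on clean signals, and keeps area <= depth * duration under noise
    depth[i] <- max(0, max(d))
    area[i] <- if (length(d) > 1L) sum((d[-1] + d[-length(d)]) / 2) else 0
  }
  ev <- data.frame(nadir_idx = nadirs, preceding_peak_idx = pk,
                   win_start = s0, win_finish = f0, baseline = baseline,
                   depth = depth, duration_s = as.numeric(f0 - s0),
                   area = area)
  structure(list(events = ev, mean_duration_s = mean(ev$duration_s)),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d events, mean duration %.1f s\n",
              nrow(x$events), x$mean_duration_s))
  invisible(x)
}

#' Detect and delineate in one call
#'
#' @inheritParams detect_valleys
#' @return an `event_set`.
#' @export
detect_events <- function(signal, min_depth = 2) {
  delineate_events(signal, detect_valleys(signal, min_depth))
}

#' Hypoxic burden
#'
#' Total desaturation area of the delineated events, converted from
#' %·s to %·min and normalized by the total recording time in hours.
#'
#' @param events an `event_set`.
#' @param trt_hours total recording time, hours (> 0).
#' @return HB in %·min/h.
#' @export
hypoxic_burden <- function(events, trt_hours) {
  stopifnot(inherits(events, "event_set"))
  if (!is.numeric(trt_hours) || trt_hours <= 0) {
    stop("total recording time must be positive", call. = FALSE)
  }
  sum(events$events$area) / 60 / trt_hours
}

#' Oxygen desaturation index
#'
#' Number of delineated events whose depth (baseline minus nadir) is at
#' least `drop_threshold` percent, per hour of sleep.
#'
#' @param events an `event_set`.
#' @param tst_hours total sleep time, hours (> 0); for recordings
#'   without staging, TST is taken equal to TRT.
#' @param drop_threshold qualifying drop, percent (default 4).
#' @return ODI in events/h.
#' @export
odi <- function(events, tst_hours, drop_threshold = 4) {
  stopifnot(inherits(events, "event_set"))
  if (!is.numeric(tst_hours) || tst_hours <= 0) {
    stop("total sleep time must be positive", call. = FALSE)
  }
  sum(events$events$depth >= drop_threshold) / tst_hours
}

#' Export an event table
#'
#' @param events an `event_set`.
#' @param subject_id identifier column value.
#' @return data.frame ready for delimited export.
#' @export
event_table <- function(events, subject_id = NA_character_) {
  cbind(subject_id = subject_id, events$events)
}
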