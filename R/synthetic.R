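#' Describe a synthetic nocturnal SpO2 profile
#'
#' The stated world of the generator: a stable per-subject baseline with
#' superimposed, non-overlapping desaturation dips and additive
#' measurement noise. Defaults describe a moderate OSA phenotype; the
#' non-OSA companion is obtained by dropping `event_rate_per_h` below
#' the 5/h labeling rule.
#'
#' @param baseline_mean,baseline_sd per-subject baseline saturation
#'   draw, percent (baseline sampled once per subject, clipped at 100).
#' @param event_rate_per_h expected desaturation events per hour
#'   (homogeneous Poisson onsets, non-overlap enforced by rejection).
#' @param depth_mean,depth_sd event depth draw, percent drop.
#' @param duration_mean,duration_sd event duration draw, seconds.
#' @param noise_sd additive Gaussian oximeter noise, percent.
#' @param duration_h recording length, hours.
#' @param shape `"raised_cosine"` (smooth nadir; default) or
#'   `"triangular"` (piecewise linear, exact-area oracle friendly).
#' @return a list of class `signal_profile`.
#' @export
signal_profile <- function(baseline_mean = 96, baseline_sd = 0.8,
                           event_rate_per_h = 30,
                           depth_mean = 8, depth_sd = 2,
                           duration_mean = 30, duration_sd = 5,
                           noise_sd = 0.3, duration_h = 8,
                           shape = c("raised_cosine", "triangular")) {
  shape <- match.arg(shape)
  stopifnot(baseline_mean > 80, baseline_mean <= 100,
            event_rate_per_h >= 0, depth_mean >= 0,
            duration_mean > 0, duration_h > 0, noise_sd >= 0)
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 event_rate_per_h = event_rate_per_h,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 noise_sd = noise_sd, duration_h = duration_h,
                 shape = shape),
            class = "signal_profile")
}

#' Generate one synthetic 1 Hz SpO2 signal
#'
#' Event onsets follow a homogeneous Poisson process at
#' `event_rate_per_h`; overlapping candidates are rejected so inserted
#' events are disjoint by construction. Each event subtracts a smooth
#' dip of sampled depth and duration from the subject baseline;
#' Gaussian noise is added and values are clipped to [40, 100].
#'
#' The generation log (one row per inserted event: onset, duration,
#' depth, and whether the depth qualifies for the 4% ODI rule) is
#' attached as `attr(, "event_log")` for oracle use.
#'
#' @param profile a [signal_profile()].
#' @param seed optional integer seed; when supplied the draw is
#'   reproducible in isolation.
#' @param subject_id identifier.
#' @return an [spo2_signal()] at 1 Hz with an `event_log` attribute.
#' @export
generate_signal <- function(profile, seed = NULL, subject_id = "synth") {
  stopifnot(inherits(profile, "signal_profile"))
  if (!is.null(seed)) set.seed(seed)
  n <- round(profile$duration_h * 3600)
  baseline <- min(100, stats::rnorm(1, profile$baseline_mean,
                                    profile$baseline_sd))
  vals <- rep(baseline, n)
  n_ev <- stats::rpois(1, profile$event_rate_per_h * profile$duration_h)
  log <- data.frame(onset = integer(0), duration = integer(0),
                    depth = numeric(0), qualifies = logical(0))
  if (n_ev > 0) {
    durations <- pmax(8, round(stats::rnorm(n_ev, profile$duration_mean,
                                            profile$duration_sd)))
    depths <- pmax(0.5, stats::rnorm(n_ev, profile$depth_mean,
                                     profile$depth_sd))
    if (sum(durations) > 0.8 * n) {
      stop("generation error: event density leaves no room for ",
           "non-overlapping placement", call. = FALSE)
    }
    onsets <- integer(0)
    kept <- integer(0)
    attempts <- 0L
    i <- 1L
    while (i <= n_ev && attempts < 50L * n_ev) {
      attempts <- attempts + 1L
      cand <- sample.int(n - durations[i] - 1L, 1)
      # require a 5 s guard band so recovery flanks stay separable
      ok <- !length(onsets) ||
        all(cand + durations[i] + 5L < onsets |
              cand > onsets + durations[kept] + 5L)
      if (ok) {
        onsets <- c(onsets, cand)
        kept <- c(kept, i)
        i <- i + 1L
      }
    }
    if (length(kept) < n_ev) {
      stop("generation error: could not place all events without overlap",
           call. = FALSE)
    }
    ord <- order(onsets)
    onsets <- onsets[ord]
    durations <- durations[kept][ord]
    depths <- depths[kept][ord]
    for (j in seq_along(onsets)) {
      L <- durations[j]
      t <- 0:L
      dip <- switch(profile$shape,
        raised_cosine = depths[j] * 0.5 * (1 - cos(2 * pi * t / L)),
        triangular = depths[j] * (1 - abs(2 * t / L - 1)))
      idx <- onsets[j] + t
      idx <- idx[idx >= 1 & idx <= n]
      vals[idx] <- vals[idx] - dip[seq_along(idx)]
    }
    log <- data.frame(onset = onsets, duration = durations, depth = depths,
                      qualifies = depths >= 4)
  }
  if (profile$noise_sd > 0) {
    vals <- vals + stats::rnorm(n, 0, profile$noise_sd)
  }
  vals <- pmin(100, pmax(40, vals))
  sig <- spo2_signal(vals, rate_hz = 1, subject_id = subject_id)
  attr(sig, "event_log") <- log
  attr(sig, "baseline") <- baseline
  sig
}

#' Generate a labeled synthetic cohort
#'
#' Draws exactly `round(n * prevalence)` OSA subjects from the OSA
#' profile and the remainder from the non-OSA profile. Labels follow
#' the AHI-style rule on the nominal event rate: a subject is OSA iff
#' its `true_event_rate` is at least 5 events/h, so the two profiles
#' must sit on opposite sides of that cut.
#'
#' @param n cohort size.
#' @param prevalence OSA proportion in (0, 1).
#' @param profiles list with elements `osa` and `non_osa`, both
#'   [signal_profile()] objects.
#' @param demographics list: `male_frac` (default 0.75), `age_median`
#'   (default 45), `age_sd` (default 12).
#' @param cohort tag stored on each subject, e.g. "internal".
#' @param seed integer master seed for the whole cohort.
#' @return a list with `subjects` (data.frame: subject_id, label, sex,
#'   age_years, cohort, true_event_rate, tst_seconds) and `signals`
#'   (named list of [spo2_signal()]).
#' @export
generate_cohort <- function(n, prevalence = 0.5,
                            profiles = list(
                              osa = signal_profile(event_rate_per_h = 30),
                              non_osa = signal_profile(event_rate_per_h = 2,
                                                       depth_mean = 5)),
                            demographics = list(male_frac = 0.75,
                                                age_median = 45,
                                                age_sd = 12),
                            cohort = "internal", seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1)
  if (profiles$osa$event_rate_per_h < 5) {
    stop("configuration error: OSA profile event rate below the 5/h rule",
         call. = FALSE)
  }
  if (profiles$non_osa$event_rate_per_h >= 5) {
    stop("configuration error: non-OSA profile event rate at or above 5/h",
         call. = FALSE)
  }
  set.seed(seed)
  n_osa <- round(n * prevalence)
  labels <- c(rep(1L, n_osa), rep(0L, n - n_osa))
  ids <- sprintf("%s_%04d", cohort, seq_len(n))
  sex <- ifelse(stats::runif(n) < demographics$male_frac, "male", "female")
  age <- pmax(18L, round(stats::rnorm(n, demographics$age_median,
                                      demographics$age_sd)))
  seeds <- sample.int(.Machine$integer.max, n)
  signals <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- if (labels[i] == 1L) profiles$osa else profiles$non_osa
    signals[[i]] <- generate_signal(prof, seed = seeds[i],
                                    subject_id = ids[i])
  }
  names(signals) <- ids
  subjects <- data.frame(
    subject_id = ids, label = labels, sex = sex, age_years = age,
    cohort = cohort,
    true_event_rate = ifelse(labels == 1L,
                             profiles$osa$event_rate_per_h,
                             profiles$non_osa$event_rate_per_h),
    tst_seconds = vapply(signals, trt_seconds, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(subjects) <- NULL
  list(subjects = subjects, signals = signals)
}

#' Write a cohort to a directory
#'
#' Signals go to `<dir>/signals/<subject_id>.csv` in the canonical
#' delimited format; the manifest to `<dir>/manifest.tsv`.
#'
#' @param cohort_obj result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort_obj, dir) {
  sigdir <- file.path(dir, "signals")
  dir.create(sigdir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort_obj$signals)) {
    write_signal(cohort_obj$signals[[id]],
                 file.path(sigdir, paste0(id, ".csv")))
  }
  utils::write.table(cohort_obj$subjects, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
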