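# Synthetic two-class CTG generator. Emulates the statistical structure
# of 2 Hz antepartum FHR recordings: a slowly drifting baseline near
# 110-160 bpm, band-limited beat-to-beat variability, transient
# raised-cosine accelerations and decelerations, and signal-loss gaps.
# Every injected component is logged as ground truth so downstream
# detectors can be validated exactly.

#' Synthetic generator configuration
#'
#' Defaults describe a healthy antepartum fetus: baseline 140 +/- 8 bpm
#' across records with a +/-3 bpm slow drift within a record; band-limited
#' variability with LF/MF/HF powers of 9/2/0.8 bpm^2; about 3
#' accelerations and 0.3 decelerations per 20 minutes; about 2 short
#' signal-loss gaps per 20 minutes (log-normal durations, median 6 s, so
#' most are interpolated and a minority are spliced). Event amplitude and
#' duration distributions are truncated normals; an event's `duration` is
#' its supra-threshold duration at the 10 bpm deviation level, which the
#' raised-cosine shape makes analytically exact.
#'
#' @param baseline_mean,baseline_sd Across-record baseline level (bpm).
#' @param drift_amp Within-record slow drift amplitude (bpm).
#' @param band_powers Named numeric `c(LF=, MF=, HF=)` variability powers
#'   (bpm^2) in 0.03-0.15 / 0.15-0.5 / 0.5-1.0 Hz.
#' @param accel_rate,decel_rate Expected events per 20 minutes.
#' @param accel_amp_mean,accel_amp_sd,accel_amp_range Acceleration peak
#'   amplitude distribution (bpm, truncated normal).
#' @param accel_dur_mean,accel_dur_sd,accel_dur_range Acceleration
#'   supra-threshold duration distribution (s).
#' @param decel_amp_mean,decel_amp_sd,decel_amp_range,decel_dur_mean,decel_dur_sd,decel_dur_range
#'   Deceleration analogues.
#' @param gap_rate Expected signal-loss gaps per 20 minutes.
#' @param gap_meanlog,gap_sdlog Log-normal gap duration parameters (s).
#' @param gw_range Gestational-week range (uniform; default 32-40).
#' @param age_mean,age_sd,age_range Maternal age (years, truncated
#'   normal).
#' @param duration_min Record duration in minutes (default 22).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(baseline_mean = 140, baseline_sd = 8,
                         drift_amp = 3,
                         band_powers = c(LF = 9, MF = 2, HF = 0.8),
                         accel_rate = 3,
                         accel_amp_mean = 18, accel_amp_sd = 4,
                         accel_amp_range = c(12, 30),
                         accel_dur_mean = 25, accel_dur_sd = 8,
                         accel_dur_range = c(17, 60),
                         decel_rate = 0.3,
                         decel_amp_mean = 25, decel_amp_sd = 8,
                         decel_amp_range = c(12, 40),
                         decel_dur_mean = 45, decel_dur_sd = 15,
                         decel_dur_range = c(20, 90),
                         gap_rate = 2, gap_meanlog = log(6), gap_sdlog = 0.8,
                         gw_range = c(32, 40),
                         age_mean = 31, age_sd = 5, age_range = c(18, 45),
                         duration_min = 22) {
  cfg <- as.list(environment())
  stopifnot(cfg$accel_rate >= 0, cfg$decel_rate >= 0, cfg$gap_rate >= 0,
            cfg$duration_min > 0, all(cfg$band_powers >= 0))
  structure(cfg, class = "synth_config")
}

#' Default class contrast for two-class datasets
#'
#' Relative to the healthy configuration, the pathological class has
#' variability band powers scaled by 0.5, acceleration rate by 0.25 and
#' deceleration rate by 3 — separable but overlapping classes that
#' exercise the classifier nontrivially. Metadata distributions are
#' identical across classes (no leakage).
#'
#' @param cfg A healthy-class [synth_config()].
#' @param variability_factor,accel_factor,decel_factor Multipliers
#'   applied for the pathological class (defaults 0.5, 0.25, 3).
#' @return The pathological-class `synth_config`.
#' @export
pathological_config <- function(cfg = synth_config(),
                                variability_factor = 0.5,
                                accel_factor = 0.25, decel_factor = 3) {
  cfg$band_powers <- cfg$band_powers * variability_factor
  cfg$accel_rate <- cfg$accel_rate * accel_factor
  cfg$decel_rate <- cfg$decel_rate * decel_factor
  cfg
}

.rtnorm <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, range[1]), range[2])
}

# Gaussian noise band-limited to [lo, hi] Hz, scaled to target variance.
.band_noise <- function(n, fs, lo, hi, power) {
  if (power <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided -> folded frequency
  keep <- freqs >= lo & freqs <= hi
  f[!keep] <- 0
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sqrt(power)
}

# Raised-cosine (Hann) bump with peak amplitude `amp` whose width is set
# so that the excursion exceeds `thr` bpm for exactly `dur_s` seconds.
.event_bump <- function(n, fs, center_idx, amp, dur_s, thr = 10) {
  c_frac <- thr / abs(amp)
  if (c_frac >= 1) return(numeric(n))  # never crosses threshold
  u0 <- acos(1 - 2 * c_frac) / (2 * pi)
  total_s <- dur_s / (1 - 2 * u0)
  half <- round(total_s * fs / 2)
  idx <- (center_idx - half):(center_idx + half)
  keep <- idx >= 1 & idx <= n
  u <- (idx[keep] - (center_idx - half)) / (2 * half)
  bump <- numeric(n)
  bump[idx[keep]] <- amp * 0.5 * (1 - cos(2 * pi * u))
  bump
}

#' Generate one synthetic CTG record with ground truth
#'
#' The FHR trace is baseline drift + band-limited Gaussian variability +
#' raised-cosine accelerations/decelerations + injected signal-loss gaps
#' (samples set to 0). Ground truth records the true baseline and every
#' injected event and gap.
#'
#' @param cfg A [synth_config()].
#' @param class_label 0 (healthy) or 1 (pathological).
#' @param seed Integer RNG seed.
#' @param record_id Identifier (default derived from seed and label).
#' @return A [ctg_record()] with a `ground_truth` attribute: list with
#'   `baseline` (bpm series), `events` (data.frame: type, center_s,
#'   amplitude, duration_s) and `gaps` (data.frame: start_s, duration_s).
#' @export
generate_record <- function(cfg = synth_config(), class_label = 0L,
                            seed = 1L, record_id = NULL) {
  set.seed(seed)
  fs <- fhr_sampling()$fs_hz
  n <- round(cfg$duration_min * 60 * fs)
  if (cfg$duration_min < 20)
    warning("record shorter than 20 minutes: segment extraction will be empty")
  if (is.null(record_id))
    record_id <- sprintf("synth_%d_%06d", class_label, seed)

  level <- stats::rnorm(1, cfg$baseline_mean, cfg$baseline_sd)
  tt <- seq_len(n) / fs
  drift <- cfg$drift_amp * (sin(2 * pi * tt / (600 + 300 * stats::runif(1)) +
                                  2 * pi * stats::runif(1)) +
                            0.5 * sin(2 * pi * tt / (1200 + 600 * stats::runif(1)) +
                                        2 * pi * stats::runif(1))) / 1.5
  baseline <- level + drift

  noise <- .band_noise(n, fs, 0.03, 0.15, cfg$band_powers[["LF"]]) +
    .band_noise(n, fs, 0.15, 0.5, cfg$band_powers[["MF"]]) +
    .band_noise(n, fs, 0.5, 1.0, cfg$band_powers[["HF"]])

  dur_factor <- cfg$duration_min / 20
  events <- data.frame(type = character(0), center_s = numeric(0),
                       amplitude = numeric(0), duration_s = numeric(0))
  bumps <- numeric(n)
  add_events <- function(kind, rate, amp_mean, amp_sd, amp_range,
                         dur_mean, dur_sd, dur_range, sign) {
    k <- stats::rpois(1, rate * dur_factor)
    if (k == 0) return()
    centers <- sort(stats::runif(k, 60, cfg$duration_min * 60 - 60))
    for (i in seq_len(k)) {
      amp <- .rtnorm(1, amp_mean, amp_sd, amp_range)
      dur <- .rtnorm(1, dur_mean, dur_sd, dur_range)
      bumps <<- bumps + .event_bump(n, fs, round(centers[i] * fs),
                                    sign * amp, dur)
      events[nrow(events) + 1L, ] <<- list(kind, centers[i], sign * amp, dur)
    }
  }
  add_events("accel", cfg$accel_rate, cfg$accel_amp_mean, cfg$accel_amp_sd,
             cfg$accel_amp_range, cfg$accel_dur_mean, cfg$accel_dur_sd,
             cfg$accel_dur_range, +1)
  add_events("decel", cfg$decel_rate, cfg$decel_amp_mean, cfg$decel_amp_sd,
             cfg$decel_amp_range, cfg$decel_dur_mean, cfg$decel_dur_sd,
             cfg$decel_dur_range, -1)

  fhr <- baseline + noise + bumps
  fhr <- pmin(pmax(fhr, 55), 215)  # keep within the physiological range

  n_gaps <- stats::rpois(1, cfg$gap_rate * dur_factor)
  gaps <- data.frame(start_s = numeric(0), duration_s = numeric(0))
  for (g in seq_len(n_gaps)) {
    dur <- stats::rlnorm(1, cfg$gap_meanlog, cfg$gap_sdlog)
    start <- stats::runif(1, 0, cfg$duration_min * 60 - dur)
    i0 <- max(1L, round(start * fs)); i1 <- min(n, i0 + round(dur * fs) - 1L)
    if (i1 >= i0) {
      fhr[i0:i1] <- 0
      gaps[nrow(gaps) + 1L, ] <- list(start, dur)
    }
  }

  gw <- stats::runif(1, cfg$gw_range[1], cfg$gw_range[2])
  age <- .rtnorm(1, cfg$age_mean, cfg$age_sd, cfg$age_range)
  rec <- ctg_record(fhr, record_id = record_id, label = class_label,
                    gestational_week = gw, maternal_age = age)
  attr(rec, "ground_truth") <- list(baseline = baseline, events = events,
                                    gaps = gaps)
  rec
}

#' Generate a balanced labeled two-class dataset
#'
#' @param n_per_class Records per class (>= 1).
#' @param cfg_healthy Healthy-class [synth_config()].
#' @param cfg_pathological Pathological-class config; default is
#'   [pathological_config()] applied to `cfg_healthy`.
#' @param seed Base RNG seed; record `i` of class `c` uses
#'   `seed + c * n_per_class + i`.
#' @return A list of class `labeled_dataset` with `records` (list of
#'   [ctg_record()]) and `labels`.
#' @export
generate_dataset <- function(n_per_class, cfg_healthy = synth_config(),
                             cfg_pathological = pathological_config(cfg_healthy),
                             seed = 1L) {
  stopifnot(n_per_class >= 1)
  records <- vector("list", 2 * n_per_class)
  labels <- integer(2 * n_per_class)
  k <- 0L
  for (cl in c(0L, 1L)) {
    cfg <- if (cl == 0L) cfg_healthy else cfg_pathological
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      records[[k]] <- generate_record(cfg, class_label = cl,
                                      seed = seed + cl * n_per_class + i - 1L)
      labels[k] <- cl
    }
  }
  structure(list(records = records, labels = labels),
            class = "labeled_dataset")
}

#' Run the full pipeline on a dataset of records
#'
#' Preprocesses every record, keeps the first acceptable segment per
#' record, extracts the 15-feature vector and the configured image stack
#' for each. Records yielding no clean segment are dropped.
#'
#' @param dataset A [generate_dataset()] result or a list of
#'   [ctg_record()] objects.
#' @param encoders Encoder names for the image stacks (default
#'   [default_encoders()]); `NULL` skips image encoding.
#' @param quality_cap Segment quality cap (see [extract_segments()]).
#' @param progress Print a dot every 50 records.
#' @return List with `features` (data.frame from [feature_table()]),
#'   `images` (64 x 64 x c x n array or `NULL`), `labels`, `segments`.
#' @export
dataset_to_inputs <- function(dataset, encoders = default_encoders(),
                              quality_cap = 0.10, progress = FALSE) {
  records <- if (inherits(dataset, "labeled_dataset")) dataset$records
             else dataset
  segs <- list()
  for (i in seq_along(records)) {
    s <- preprocess_record(records[[i]], quality_cap = quality_cap)
    if (length(s) > 0) segs[[length(segs) + 1L]] <- s[[1]]
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  if (length(segs) == 0) stop("no record produced a clean segment")
  feats <- feature_table(segs)
  imgs <- NULL
  if (!is.null(encoders)) {
    imgs <- array(0, c(64, 64, length(encoders), length(segs)))
    for (i in seq_along(segs))
      imgs[, , , i] <- encode_stack(segs[[i]], encoders)
  }
  list(features = feats, images = imgs,
       labels = vapply(segs, function(s) s$label, integer(1)),
       segments = segs)
}
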