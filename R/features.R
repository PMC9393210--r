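# The 15-regressor computerized-CTG feature panel per 20-minute segment:
# DELTA, II, STV, LTI (time domain on the 2.5-s interval series), LF, MF,
# HF, LF/(MF+HF) (Welch PSD of the 2 Hz interval signal), ApEn, baseline
# mean (FHRB), small/large acceleration and deceleration counts, plus
# gestational week and maternal age.

#' Names of the 15 regressors, in canonical order
#' @return Character vector of length 15.
#' @export
feature_names <- function() {
  c("DELTA", "II", "STV", "LTI", "LF", "MF", "HF", "ratio", "ApEn",
    "FHRB", "small_accels", "large_accels", "decels",
    "gestational_week", "maternal_age")
}

#' Resample a segment to the 2.5-second interbeat-interval series (T24)
#'
#' Classical computerized-CTG variability indices operate on 24 interval
#' values per minute: the 2 Hz bpm trace is block-averaged over 5-sample
#' (2.5 s) windows and converted to milliseconds as `T = 60000 / bpm`.
#'
#' @param segment An [fhr_segment()] (2400 samples) or a numeric vector
#'   whose length is a multiple of 5.
#' @return Numeric vector of interval values in ms (480 for a full
#'   segment), with attribute `minutes`.
#' @export
#' @examples
#' seg <- fhr_segment(rep(120, 2400))
#' all(to_t24(seg) == 500)  # 60000 / 120
to_t24 <- function(segment) {
  x <- if (inherits(segment, "fhr_segment")) segment$fhr else as.numeric(segment)
  if (length(x) %% 5 != 0) stop("length must be a multiple of 5 samples")
  bpm <- colMeans(matrix(x, nrow = 5))
  if (any(bpm <= 0)) stop("non-positive bpm block mean; run preprocessing first")
  t24 <- 60000 / bpm
  attr(t24, "minutes") <- length(t24) / 24
  t24
}

#' Classical time-domain variability indices on the T24 series
#'
#' Per minute `j` with 24 interval values: `STV(j)` is the mean absolute
#' successive difference, `DELTA(j)` the minute range (max - min), and
#' `II(j)` the standard deviation of the absolute successive differences
#' divided by `STV(j)` (0 when `STV(j)` is 0). STV, DELTA and II are the
#' means over complete minutes. LTI is the interquartile range of
#' `m(i) = sqrt(T(i)^2 + T(i+1)^2)` computed over non-overlapping 3-minute
#' windows and averaged over windows.
#'
#' @param t24 Interval series from [to_t24()] (ms).
#' @return Named list with `STV`, `DELTA`, `II` (ms, ms, unitless) and
#'   `LTI` (ms).
#' @export
time_domain_indices <- function(t24) {
  n_min <- length(t24) %/% 24
  if (n_min < 1) stop("at least one complete minute is required")
  if (n_min < 3) stop("LTI requires at least 3 complete minutes")
  t24 <- t24[seq_len(n_min * 24)]
  m <- matrix(t24, nrow = 24)  # one column per minute
  ad <- abs(m[-1, , drop = FALSE] - m[-24, , drop = FALSE])  # 23 x n_min
  stv_j <- colMeans(ad)
  delta_j <- apply(m, 2, max) - apply(m, 2, min)
  sd_j <- apply(ad, 2, stats::sd)
  ii_j <- ifelse(stv_j > 0, sd_j / stv_j, 0)

  n_win <- n_min %/% 3
  lti_w <- vapply(seq_len(n_win), function(w) {
    seg <- t24[((w - 1) * 72 + 1):(w * 72)]
    mm <- sqrt(seg[-72]^2 + seg[-1]^2)
    stats::IQR(mm)
  }, numeric(1))

  list(STV = mean(stv_j), DELTA = mean(delta_j), II = mean(ii_j),
       LTI = mean(lti_w))
}

# Welch power spectral density of a uniformly sampled series.
# Hann-windowed overlapping segments, per-segment linear detrend,
# one-sided density normalized so that sum(psd) * df ~ variance.
.welch_psd <- function(x, fs, nwin = 240, overlap = 0.5) {
  n <- length(x)
  nwin <- min(nwin, n)
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- as.numeric(signal::hanning(nwin))
  u <- sum(w^2)
  nf <- nwin %/% 2 + 1L
  acc <- numeric(nf)
  tt <- seq_len(nwin)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    fit <- stats::lm.fit(cbind(1, tt), seg)  # linear detrend
    seg <- fit$residuals * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- Mod(X)^2 / (fs * u)
    # one-sided doubling (not DC; not Nyquist for even nwin)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nwin %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nf) - 1L) * fs / nwin, psd = acc / length(starts),
       df = fs / nwin)
}

#' Frequency-domain band powers of an FHR segment
#'
#' The 2 Hz bpm trace is converted to an interval signal in ms
#' (`60000 / bpm`), its power spectral density estimated by Welch's method
#' (2-minute Hann windows, 50% overlap, per-window linear detrend), and
#' integrated over the fetal HRV bands: LF 0.03-0.15 Hz, MF 0.15-0.5 Hz,
#' HF 0.5-1.0 Hz. The sympathovagal-style ratio is `LF / (MF + HF)`.
#'
#' @param segment An [fhr_segment()] or numeric bpm vector at 2 Hz.
#' @param nwin,overlap Welch window length (samples) and overlap fraction.
#' @return Named list `LF`, `MF`, `HF` (ms^2), `ratio` (unitless; `NA` if
#'   `MF + HF` is zero) and `total` (power over 0.03-1.0 Hz, ms^2).
#' @export
spectral_powers <- function(segment, nwin = 240, overlap = 0.5) {
  x <- if (inherits(segment, "fhr_segment")) segment$fhr else as.numeric(segment)
  if (any(x <= 0)) stop("non-positive bpm sample; run preprocessing first")
  ms <- 60000 / x
  pw <- .welch_psd(ms, fs = fhr_sampling()$fs_hz, nwin = nwin, overlap = overlap)
  band <- function(lo, hi, lo_open = FALSE) {
    sel <- if (lo_open) pw$freq > lo & pw$freq <= hi
           else pw$freq >= lo & pw$freq <= hi
    sum(pw$psd[sel]) * pw$df
  }
  lf <- band(0.03, 0.15)
  mf <- band(0.15, 0.5, lo_open = TRUE)
  hf <- band(0.5, 1.0, lo_open = TRUE)
  ratio <- if ((mf + hf) > 0) lf / (mf + hf) else NA_real_
  list(LF = lf, MF = mf, HF = hf, ratio = ratio, total = band(0.03, 1.0))
}

#' Approximate entropy (ApEn)
#'
#' Regularity statistic of Pincus: `ApEn(m, r) = Phi^m(r) - Phi^{m+1}(r)`
#' where `Phi^m(r)` is the mean over template positions `i` of
#' `ln(C_i^m(r))`, and `C_i^m(r)` is the fraction of length-`m` templates
#' within Chebyshev distance `r` of template `i` (self-matches included).
#' Lower values indicate more regular dynamics.
#'
#' @param x Numeric series.
#' @param m Embedding (template) length, default 2.
#' @param r Tolerance; default `0.2 * sd(x)`.
#' @return ApEn in nats.
#' @export
#' @examples
#' approximate_entropy(rep(5, 50))  # 0: perfectly regular
approximate_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  x <- as.numeric(x)
  n <- length(x)
  if (n <= m + 1) stop("series too short for embedding length m")
  if (!is.finite(r) || r <= 0) {
    # constant series: sd = 0; all templates match trivially
    if (stats::sd(x) == 0) return(0)
    stop("tolerance r must be positive")
  }
  phi <- function(mm) {
    nt <- n - mm + 1L
    # Chebyshev distances via running max over lagged absolute differences
    d <- abs(outer(x[seq_len(nt)], x[seq_len(nt)], "-"))
    if (mm > 1) for (k in seq_len(mm - 1L)) {
      idx <- seq_len(nt) + k
      d <- pmax(d, abs(outer(x[idx], x[idx], "-")))
    }
    mean(log(rowMeans(d <= r)))
  }
  phi(m) - phi(m + 1L)
}

#' FHR baseline by iterative excursion trimming
#'
#' A simplified Mantel-style baseline: the trace is low-pass filtered with
#' a 2-minute moving average, then samples deviating more than
#' `excl_bpm` from the current baseline estimate are replaced by that
#' estimate and the filter re-applied, until the estimate changes by less
#' than `tol` bpm or `max_iter` iterations. This removes accelerative and
#' decelerative excursions from the reference level. `FHRB` is the mean of
#' the baseline over the segment.
#'
#' @param segment An [fhr_segment()] or numeric bpm vector.
#' @param win_s Moving-average window in seconds (default 120).
#' @param excl_bpm Exclusion threshold in bpm (default 10).
#' @param tol Convergence tolerance in bpm (default 0.1).
#' @param max_iter Maximum iterations (default 10).
#' @return List with `baseline` (bpm series, same length) and `FHRB`
#'   (mean baseline, bpm).
#' @export
baseline_mantel <- function(segment, win_s = 120, excl_bpm = 10,
                            tol = 0.1, max_iter = 10) {
  x <- if (inherits(segment, "fhr_segment")) segment$fhr else as.numeric(segment)
  n <- length(x)
  w <- min(win_s * fhr_sampling()$fs_hz, n)
  movavg <- function(v) {
    # centred moving average with edge replication
    pad <- c(rep(v[1], w), v, rep(v[n], w))
    cs <- cumsum(pad)
    half <- w %/% 2
    i <- seq_len(n) + w
    (cs[i + half] - cs[i - (w - half)]) / w
  }
  b <- movavg(x)
  work <- x
  for (it in seq_len(max_iter)) {
    excl <- abs(x - b) > excl_bpm
    work <- ifelse(excl, b, x)
    b_new <- movavg(work)
    if (max(abs(b_new - b)) < tol) { b <- b_new; break }
    b <- b_new
  }
  list(baseline = b, FHRB = mean(b))
}

# Count qualifying runs given a deviation series (bpm above/below baseline,
# positive = in the event direction) and clause list; each clause is
# c(threshold_bpm, min_duration_s). Runs are maximal stretches where the
# deviation exceeds the *lowest* clause threshold; a run is one event if
# any clause is satisfied within it (contiguously at that clause's own
# threshold).
.count_events <- function(dev, clauses, fs) {
  base_thr <- min(vapply(clauses, `[`, numeric(1), 1))
  runs <- .runs_of(dev > base_thr)
  if (nrow(runs) == 0) return(list(count = 0L, peaks = numeric(0)))
  hit <- logical(nrow(runs))
  peaks <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    seg <- dev[runs$start[i]:runs$end[i]]
    peaks[i] <- max(seg)
    for (cl in clauses) {
      thr <- cl[1]; min_len <- cl[2] * fs
      sub <- .runs_of(seg > thr)
      if (nrow(sub) > 0 && max(sub$len) >= min_len) { hit[i] <- TRUE; break }
    }
  }
  list(count = sum(hit), peaks = peaks[hit], hit = hit, runs = runs)
}

#' Detect accelerations and decelerations against a baseline
#'
#' An acceleration candidate is a maximal run with FHR more than 10 bpm
#' above baseline sustained for at least 15 s; it is counted as large if
#' its peak deviation exceeds 15 bpm, otherwise as small (an event is never
#' counted twice). A deceleration is a maximal run below baseline whose
#' deviation exceeds 20 bpm contiguously for at least 30 s, or exceeds
#' 10 bpm contiguously for at least 60 s.
#'
#' @param segment An [fhr_segment()] or numeric bpm vector.
#' @param baseline Baseline series from [baseline_mantel()] (bpm, same
#'   length); computed if omitted.
#' @return Named list of integer counts `small_accels`, `large_accels`,
#'   `decels`.
#' @export
detect_events <- function(segment, baseline = NULL) {
  x <- if (inherits(segment, "fhr_segment")) segment$fhr else as.numeric(segment)
  if (is.null(baseline)) baseline <- baseline_mantel(x)$baseline
  fs <- fhr_sampling()$fs_hz
  dev_up <- x - baseline
  acc <- .count_events(dev_up, list(c(10, 15)), fs)
  n_large <- sum(acc$peaks > 15)
  n_small <- acc$count - n_large
  dec <- .count_events(baseline - x, list(c(20, 30), c(10, 60)), fs)
  list(small_accels = as.integer(n_small),
       large_accels = as.integer(n_large),
       decels = as.integer(dec$count))
}

#' Extract the full 15-regressor vector for one segment
#'
#' @param segment An [fhr_segment()].
#' @param apen_m,apen_r_factor ApEn embedding length and tolerance factor
#'   (`r = apen_r_factor * sd(T24)`); defaults 2 and 0.2.
#' @return Named numeric vector of length 15 in [feature_names()] order,
#'   with attributes `record_id`, `start_offset` and `label`.
#' @export
extract_features <- function(segment, apen_m = 2, apen_r_factor = 0.2) {
  stopifnot(inherits(segment, "fhr_segment"))
  t24 <- to_t24(segment)
  td <- time_domain_indices(t24)
  sp <- spectral_powers(segment)
  r <- apen_r_factor * stats::sd(t24)
  apen <- if (r > 0) approximate_entropy(t24, m = apen_m, r = r) else 0
  bl <- baseline_mantel(segment)
  ev <- detect_events(segment, bl$baseline)
  v <- c(DELTA = td$DELTA, II = td$II, STV = td$STV, LTI = td$LTI,
         LF = sp$LF, MF = sp$MF, HF = sp$HF, ratio = sp$ratio,
         ApEn = apen, FHRB = bl$FHRB,
         small_accels = ev$small_accels, large_accels = ev$large_accels,
         decels = ev$decels,
         gestational_week = segment$gestational_week,
         maternal_age = segment$maternal_age)
  v <- v[feature_names()]
  attr(v, "record_id") <- segment$record_id
  attr(v, "start_offset") <- segment$start_offset
  attr(v, "label") <- segment$label
  v
}

#' Build a feature table from a list of segments
#'
#' @param segments List of [fhr_segment()] objects.
#' @param ... Passed to [extract_features()].
#' @return A data.frame with columns `record_id`, `start_offset`, `label`
#'   and the 15 regressors.
#' @export
feature_table <- function(segments, ...) {
  rows <- lapply(segments, function(s) {
    v <- extract_features(s, ...)
    cbind(data.frame(record_id = attr(v, "record_id"),
                     start_offset = attr(v, "start_offset"),
                     label = attr(v, "label")),
          as.data.frame(as.list(v)))
  })
  do.call(rbind, rows)
}

#' Fit a min-max scaler on the training partition
#'
#' Per-column minima and maxima are learned on training rows only and
#' reused for test rows, preventing information leakage. Constant columns
#' are mapped to 0 with a warning.
#'
#' @param x Data.frame or matrix of raw feature values (training rows).
#' @return An object of class `feature_scaler`.
#' @export
fit_feature_scaler <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  const <- maxs <= mins
  if (any(const))
    warning("constant feature column(s) mapped to 0: ",
            paste(colnames(x)[const], collapse = ", "))
  structure(list(mins = mins, maxs = maxs, const = const,
                 names = colnames(x)),
            class = "feature_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Values are scaled to `(x - min) / (max - min)`; values outside the
#' training range (possible on test rows) are clipped to `[0, 1]`.
#'
#' @param scaler A [fit_feature_scaler()] result.
#' @param x Data.frame or matrix with the same columns.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
apply_feature_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(scaler$mins))
  out <- sweep(x, 2, scaler$mins, "-")
  rng <- scaler$maxs - scaler$mins
  rng[scaler$const] <- 1
  out <- sweep(out, 2, rng, "/")
  out[, scaler$const] <- 0
  pmin(pmax(out, 0), 1)
}
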