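# Preprocessing: raw 2 Hz FHR traces -> clean 2400-sample (20 min) segments.
#
# Sampling convention throughout the package: 2 Hz, so one minute of
# recording is 120 samples and a 20-minute segment is 2400 samples.

#' Sampling constants
#'
#' The FHR sampling convention used throughout the package: 2 Hz sampling,
#' 120 samples per minute, 2400 samples per 20-minute analysis segment.
#'
#' @return A named list with `fs_hz`, `samples_per_minute` and
#'   `segment_samples`.
#' @export
#' @examples
#' fhr_sampling()$segment_samples  # 2400
fhr_sampling <- function() {
  list(fs_hz = 2, samples_per_minute = 120, segment_samples = 2400)
}

#' Construct a raw CTG record
#'
#' Bundles an FHR trace in beats per minute with its validity mask and
#' per-record metadata. The validity mask is computed with
#' [mark_signal_loss()] unless supplied.
#'
#' @param fhr Numeric vector of FHR samples in bpm at 2 Hz. Zeros or
#'   `NA`s denote transducer signal loss.
#' @param record_id Opaque identifier string.
#' @param label Binary class label: 0 = healthy, 1 = pathological.
#' @param gestational_week Gestational age in weeks.
#' @param maternal_age Maternal age in years.
#' @param valid_mask Optional logical vector, `TRUE` where the sample is
#'   physiologically valid. Defaults to [mark_signal_loss()] on `fhr`.
#' @param lo,hi Physiological validity range in bpm used when the mask is
#'   derived (defaults 50 and 220).
#' @return An object of class `ctg_record`.
#' @export
ctg_record <- function(fhr, record_id = "rec", label = 0L,
                       gestational_week = NA_real_, maternal_age = NA_real_,
                       valid_mask = NULL, lo = 50, hi = 220) {
  fhr <- as.numeric(fhr)
  if (length(fhr) == 0L) stop("FHR trace is empty: no data to process")
  if (!label %in% c(0, 1)) stop("label must be 0 (healthy) or 1 (pathological)")
  if (is.null(valid_mask)) valid_mask <- mark_signal_loss(fhr, lo = lo, hi = hi)
  if (length(valid_mask) != length(fhr))
    stop("fhr and valid_mask must have equal length")
  structure(
    list(fhr = fhr, valid_mask = valid_mask, label = as.integer(label),
         gestational_week = gestational_week, maternal_age = maternal_age,
         record_id = record_id),
    class = "ctg_record"
  )
}

#' @export
print.ctg_record <- function(x, ...) {
  cat(sprintf(
    "<ctg_record %s> %d samples (%.1f min at 2 Hz), label=%d, %.1f%% valid\n",
    x$record_id, length(x$fhr), length(x$fhr) / 120, x$label,
    100 * mean(x$valid_mask)))
  invisible(x)
}

#' Mark signal-loss samples in an FHR trace
#'
#' A sample is valid iff it is finite and lies in the closed physiological
#' range `[lo, hi]` bpm. Zero readings (ultrasound transducer loss) and
#' `NA`s fall outside the range and are marked invalid.
#'
#' @param fhr Numeric vector of FHR values in bpm.
#' @param lo,hi Validity bounds in bpm (inclusive). Defaults 50 and 220.
#' @return Logical vector, `TRUE` where the sample is valid.
#' @export
#' @examples
#' mark_signal_loss(c(140, 0, 150))  # TRUE FALSE TRUE
mark_signal_loss <- function(fhr, lo = 50, hi = 220) {
  if (length(fhr) == 0L) stop("FHR trace is empty: no data to process")
  is.finite(fhr) & fhr >= lo & fhr <= hi
}

# Maximal runs of a logical vector; returns data.frame(start, end, len)
# for runs where the value is TRUE.
.runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}

#' Repair signal losses by interpolation or splicing
#'
#' Maximal runs of invalid samples shorter than `max_interp_s` seconds
#' (strictly: fewer than `max_interp_s * 2` samples at 2 Hz) are filled by
#' linear interpolation between the flanking valid samples. Longer runs,
#' and runs touching either end of the record (which have no flanking
#' sample on one side), are spliced out entirely, shortening the trace.
#'
#' @param record A [ctg_record()].
#' @param max_interp_s Maximum interpolatable gap duration in seconds
#'   (default 15; gaps of exactly 15 s are spliced).
#' @return A list with `fhr` (repaired trace), `interp_mask` (logical,
#'   `TRUE` for interpolated samples), `n_spliced` (samples removed) and
#'   the original record's metadata fields.
#' @export
repair_gaps <- function(record, max_interp_s = 15) {
  stopifnot(inherits(record, "ctg_record"))
  fs <- fhr_sampling()$fs_hz
  x <- record$fhr
  ok <- record$valid_mask
  n <- length(x)
  if (!any(ok)) stop("record has no valid samples")
  max_len <- max_interp_s * fs  # runs with len < max_len are interpolated

  interp <- logical(n)
  drop <- logical(n)
  gaps <- .runs_of(!ok)
  if (nrow(gaps) > 0) {
    for (g in seq_len(nrow(gaps))) {
      s <- gaps$start[g]; e <- gaps$end[g]; len <- gaps$len[g]
      boundary <- (s == 1L) || (e == n)
      if (len < max_len && !boundary) {
        # linear ramp between the flanking valid samples
        x0 <- x[s - 1L]; x1 <- x[e + 1L]
        x[s:e] <- x0 + (x1 - x0) * seq_len(len) / (len + 1)
        interp[s:e] <- TRUE
      } else {
        drop[s:e] <- TRUE
      }
    }
  }
  list(fhr = x[!drop],
       interp_mask = interp[!drop],
       n_spliced = sum(drop),
       record_id = record$record_id,
       label = record$label,
       gestational_week = record$gestational_week,
       maternal_age = record$maternal_age)
}

#' Construct an FHR segment
#'
#' A clean, fixed-length analysis window of exactly 2400 samples (20
#' minutes at 2 Hz).
#'
#' @param fhr Numeric vector of exactly 2400 bpm values.
#' @param interpolated_fraction Fraction of samples that were filled by
#'   interpolation during gap repair.
#' @param record_id,label,gestational_week,maternal_age Provenance and
#'   metadata carried from the source record.
#' @param start_offset 0-based sample offset of the window in the repaired
#'   trace.
#' @return An object of class `fhr_segment`.
#' @export
fhr_segment <- function(fhr, interpolated_fraction = 0, record_id = "rec",
                        label = 0L, gestational_week = NA_real_,
                        maternal_age = NA_real_, start_offset = 0L) {
  seg_len <- fhr_sampling()$segment_samples
  if (length(fhr) != seg_len)
    stop(sprintf("segment must contain exactly %d samples", seg_len))
  structure(
    list(fhr = as.numeric(fhr),
         interpolated_fraction = interpolated_fraction,
         record_id = record_id, label = as.integer(label),
         gestational_week = gestational_week, maternal_age = maternal_age,
         start_offset = as.integer(start_offset)),
    class = "fhr_segment"
  )
}

#' @export
print.fhr_segment <- function(x, ...) {
  cat(sprintf(
    "<fhr_segment %s+%d> 2400 samples, label=%d, %.1f%% interpolated\n",
    x$record_id, x$start_offset, x$label, 100 * x$interpolated_fraction))
  invisible(x)
}

#' Tile a repaired record into fixed-length segments
#'
#' Non-overlapping consecutive windows of `segment_len` samples are taken
#' from the start of the repaired trace; the trailing remainder is
#' discarded. Windows whose interpolated fraction exceeds `quality_cap`
#' are rejected as too corrupted.
#'
#' @param repaired Result of [repair_gaps()].
#' @param segment_len Window length in samples (default 2400 = 20 min).
#' @param quality_cap Maximum tolerated fraction of interpolated samples
#'   per segment (default 0.10).
#' @return A list of [fhr_segment()] objects (possibly empty).
#' @export
extract_segments <- function(repaired, segment_len = 2400,
                             quality_cap = 0.10) {
  x <- repaired$fhr
  im <- repaired$interp_mask
  n_win <- length(x) %/% segment_len
  segs <- list()
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * segment_len + 1L):(w * segment_len)
    frac <- mean(im[idx])
    if (frac > quality_cap) next
    segs[[length(segs) + 1L]] <- fhr_segment(
      x[idx], interpolated_fraction = frac,
      record_id = repaired$record_id, label = repaired$label,
      gestational_week = repaired$gestational_week,
      maternal_age = repaired$maternal_age,
      start_offset = (w - 1L) * segment_len)
  }
  segs
}

#' Preprocess a raw record end to end
#'
#' Convenience wrapper: gap repair followed by segmentation.
#'
#' @inheritParams repair_gaps
#' @inheritParams extract_segments
#' @return A list of [fhr_segment()] objects.
#' @export
preprocess_record <- function(record, max_interp_s = 15, segment_len = 2400,
                              quality_cap = 0.10) {
  extract_segments(repair_gaps(record, max_interp_s = max_interp_s),
                   segment_len = segment_len, quality_cap = quality_cap)
}
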