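# CSV dialects: a record is `<id>.csv` with header time_s,fhr_bpm (one
# row per 0.5 s sample; 0 or empty = signal loss) plus a YAML sidecar
# `<id>.meta` with record_id, label, gestational_week, maternal_age.
# Segments use the same dialect with segment provenance in the sidecar.

#' Write a CTG record to CSV + metadata sidecar
#'
#' @param record A [ctg_record()].
#' @param dir Output directory (created if missing).
#' @param ground_truth Also write `<id>_events.csv` when the record
#'   carries synthetic ground truth (default TRUE).
#' @return Invisibly, the path of the CSV file.
#' @export
write_ctg_record <- function(record, dir, ground_truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- fhr_sampling()$fs_hz
  fhr <- record$fhr
  fhr[!record$valid_mask] <- 0
  path <- file.path(dir, paste0(record$record_id, ".csv"))
  utils::write.csv(data.frame(time_s = (seq_along(fhr) - 1) / fs,
                              fhr_bpm = fhr),
                   path, row.names = FALSE)
  meta <- list(record_id = record$record_id, label = record$label,
               gestational_week = record$gestational_week,
               maternal_age = record$maternal_age)
  yaml::write_yaml(meta, file.path(dir, paste0(record$record_id, ".meta")))
  gt <- attr(record, "ground_truth")
  if (ground_truth && !is.null(gt))
    utils::write.csv(gt$events,
                     file.path(dir, paste0(record$record_id, "_events.csv")),
                     row.names = FALSE)
  invisible(path)
}

#' Read a CTG record from CSV + metadata sidecar
#'
#' @param path Path to the record CSV; the `.meta` sidecar is looked up
#'   next to it.
#' @return A [ctg_record()].
#' @export
read_ctg_record <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "fhr_bpm") %in% names(d)))
  fhr <- d$fhr_bpm
  fhr[is.na(fhr)] <- 0
  meta_path <- sub("\\.csv$", ".meta", path)
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  ctg_record(fhr,
             record_id = meta$record_id %||% sub("\\.csv$", "", basename(path)),
             label = meta$label %||% 0L,
             gestational_week = meta$gestational_week %||% NA_real_,
             maternal_age = meta$maternal_age %||% NA_real_)
}

#' Write an FHR segment to CSV + metadata sidecar
#'
#' @param segment An [fhr_segment()].
#' @param dir Output directory.
#' @return Invisibly, the CSV path.
#' @export
write_segment <- function(segment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- fhr_sampling()$fs_hz
  id <- sprintf("%s_seg%06d", segment$record_id, segment$start_offset)
  path <- file.path(dir, paste0(id, ".csv"))
  utils::write.csv(data.frame(time_s = (seq_along(segment$fhr) - 1) / fs,
                              fhr_bpm = segment$fhr),
                   path, row.names = FALSE)
  yaml::write_yaml(list(record_id = segment$record_id,
                        start_offset = segment$start_offset,
                        label = segment$label,
                        interpolated_fraction = segment$interpolated_fraction,
                        gestational_week = segment$gestational_week,
                        maternal_age = segment$maternal_age),
                   file.path(dir, paste0(id, ".meta")))
  invisible(path)
}

#' Read an FHR segment written by [write_segment()]
#'
#' @param path Path to the segment CSV.
#' @return An [fhr_segment()].
#' @export
read_segment <- function(path) {
  d <- utils::read.csv(path)
  meta <- yaml::read_yaml(sub("\\.csv$", ".meta", path))
  fhr_segment(d$fhr_bpm,
              interpolated_fraction = meta$interpolated_fraction %||% 0,
              record_id = meta$record_id, label = meta$label %||% 0L,
              gestational_week = meta$gestational_week %||% NA_real_,
              maternal_age = meta$maternal_age %||% NA_real_,
              start_offset = meta$start_offset %||% 0L)
}
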