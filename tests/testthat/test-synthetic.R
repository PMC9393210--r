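# Synthetic CTG generator: determinism, degenerate configs, ground-truth
# recovery, and the configured class contrasts.

test_that("generation is deterministic under a fixed seed", {
  r1 <- generate_record(synth_config(), 0L, seed = 10)
  r2 <- generate_record(synth_config(), 0L, seed = 10)
  expect_identical(r1$fhr, r2$fhr)
  expect_identical(attr(r1, "ground_truth")$events,
                   attr(r2, "ground_truth")$events)
  r3 <- generate_record(synth_config(), 0L, seed = 11)
  expect_false(identical(r1$fhr, r3$fhr))
})

test_that("zero rates and powers give a drifting baseline only", {
  cfg <- synth_config(band_powers = c(LF = 0, MF = 0, HF = 0),
                      accel_rate = 0, decel_rate = 0, gap_rate = 0,
                      drift_amp = 0, baseline_sd = 0)
  r <- generate_record(cfg, 0L, seed = 1)
  expect_true(all(abs(r$fhr - 140) < 1e-9))
  expect_true(all(r$valid_mask))
})

test_that("records respect the validity range outside injected gaps", {
  for (seed in 1:5) {
    r <- generate_record(synth_config(), 1L, seed = seed)
    gt <- attr(r, "ground_truth")
    ok <- r$fhr[r$valid_mask]
    expect_true(all(ok >= 50 & ok <= 220))
    expect_true(all(r$fhr[!r$valid_mask] == 0))
  }
})

test_that("metadata follows the configured distributions", {
  gw <- age <- numeric(40)
  for (i in 1:40) {
    r <- generate_record(synth_config(), 0L, seed = 100 + i)
    gw[i] <- r$gestational_week; age[i] <- r$maternal_age
  }
  expect_true(all(gw >= 32 & gw <= 40))
  expect_true(all(age >= 18 & age <= 45))
})

test_that("injected accelerations with margins are recovered downstream", {
  # amplitudes and durations comfortably above the large-accel thresholds,
  # no noise so the detector sees exactly the injected events
  cfg <- synth_config(band_powers = c(LF = 0, MF = 0, HF = 0),
                      accel_rate = 3, decel_rate = 0, gap_rate = 0,
                      drift_amp = 0.5,
                      accel_amp_mean = 18, accel_amp_sd = 0.5,
                      accel_amp_range = c(17, 20),
                      accel_dur_mean = 20, accel_dur_sd = 1,
                      accel_dur_range = c(18, 25),
                      duration_min = 20)
  hits <- 0L; total <- 0L
  for (seed in 1:8) {
    r <- generate_record(cfg, 0L, seed = seed)
    ev <- attr(r, "ground_truth")$events
    ev <- ev[ev$type == "accel", ]
    # only score seeds whose events are well separated (no merged runs)
    if (nrow(ev) > 1 && min(diff(sort(ev$center_s))) < 120) next
    seg <- preprocess_record(r)[[1]]
    det <- detect_events(seg)
    expect_equal(det$large_accels, nrow(ev))
    hits <- hits + 1L
  }
  expect_gte(hits, 4)  # the check ran on a meaningful number of records
})

test_that("balanced datasets carry the configured class contrast", {
  ds <- generate_dataset(5, seed = 2)
  expect_length(ds$records, 10)
  expect_equal(sum(ds$labels), 5)

  # STV ordering: healthy variability is double the pathological power,
  # so mean STV(healthy) > mean STV(pathological) over many records
  n <- 60
  cfg_h <- synth_config(gap_rate = 0, duration_min = 20)
  cfg_p <- pathological_config(cfg_h)
  stv_h <- stv_p <- numeric(n)
  for (i in seq_len(n)) {
    sh <- preprocess_record(generate_record(cfg_h, 0L, seed = 1000 + i))[[1]]
    sp <- preprocess_record(generate_record(cfg_p, 1L, seed = 5000 + i))[[1]]
    stv_h[i] <- time_domain_indices(to_t24(sh))$STV
    stv_p[i] <- time_domain_indices(to_t24(sp))$STV
  }
  expect_gt(mean(stv_h), mean(stv_p))
})

test_that("empirical band powers scale with the configured powers", {
  base <- c(LF = 9, MF = 2, HF = 0.8)
  mean_lf <- function(fac, seeds) {
    cfg <- synth_config(band_powers = base * fac, accel_rate = 0,
                        decel_rate = 0, gap_rate = 0, duration_min = 20)
    mean(vapply(seeds, function(s) {
      seg <- preprocess_record(generate_record(cfg, 0L, seed = s))[[1]]
      spectral_powers(seg)$LF
    }, numeric(1)))
  }
  seeds <- 300:309
  lf <- vapply(c(0.25, 1, 4), function(f) mean_lf(f, seeds), numeric(1))
  expect_true(all(diff(lf) > 0))  # monotone in the configured power
})

test_that("the record/segment CSV dialect round-trips", {
  dir <- withr::local_tempdir()
  r <- generate_record(synth_config(), 1L, seed = 77)
  write_ctg_record(r, dir)
  r2 <- read_ctg_record(file.path(dir, paste0(r$record_id, ".csv")))
  expect_equal(r2$fhr[r$valid_mask], r$fhr[r$valid_mask])
  expect_identical(r2$valid_mask, r$valid_mask)
  expect_equal(r2$label, 1L)
  expect_equal(r2$gestational_week, r$gestational_week, tolerance = 1e-6)

  seg <- preprocess_record(r)[[1]]
  p <- write_segment(seg, dir)
  seg2 <- read_segment(p)
  expect_equal(seg2$fhr, seg$fhr, tolerance = 1e-6)
  expect_equal(seg2$label, seg$label)
  expect_equal(seg2$start_offset, seg$start_offset)
})
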