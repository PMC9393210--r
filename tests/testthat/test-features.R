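# The 15-regressor panel: interval resampling, time-domain indices,
# band powers, approximate entropy, baseline, event detection, scaling.

test_that("T24 resampling converts block-averaged bpm to ms intervals", {
  expect_true(all(to_t24(const_segment(120)) == 500))
  expect_true(all(abs(to_t24(const_segment(150)) - 400) < 1e-12))
  expect_length(to_t24(const_segment()), 480)
  expect_error(to_t24(1:7), "multiple of 5")
})

test_that("time-domain indices match hand computation on an alternating series", {
  # alternating 430/440 ms: |successive differences| all 10
  t24 <- rep(c(430, 440), 240)
  td <- time_domain_indices(t24)
  expect_equal(td$STV, 10)
  expect_equal(td$DELTA, 10)
  expect_equal(td$II, 0)  # zero spread of identical |differences|

  const <- time_domain_indices(rep(500, 480))
  expect_equal(const$STV, 0)
  expect_equal(const$DELTA, 0)
  expect_equal(const$LTI, 0)
  expect_error(time_domain_indices(rep(500, 48)), "3 complete minutes")
})

test_that("time-domain indices equal the per-minute loop oracle", {
  set.seed(3)
  for (case in 1:5) {
    t24 <- 420 + rnorm(480, sd = 15)
    got <- time_domain_indices(t24)
    want <- time_domain_oracle(t24)
    for (k in c("STV", "DELTA", "II", "LTI"))
      expect_equal(got[[k]], want[[k]], tolerance = 1e-12)
  }
})

test_that("band powers localize sinusoids and vanish on constants", {
  lf <- spectral_powers(sine_segment(0.10))
  expect_gt(lf$LF / (lf$LF + lf$MF + lf$HF), 0.95)
  expect_gt(lf$ratio, 1)

  mf <- spectral_powers(sine_segment(0.30))
  expect_gt(mf$MF, mf$LF)
  expect_gt(mf$MF, mf$HF)

  const <- spectral_powers(const_segment())
  expect_lt(const$LF + const$MF + const$HF, 1e-12)

  # band partition: LF+MF+HF never exceeds the total 0.03-1.0 Hz power
  set.seed(9)
  s <- fhr_segment(140 + rnorm(2400, sd = 3))
  sp <- spectral_powers(s)
  expect_lte(sp$LF + sp$MF + sp$HF, sp$total * (1 + 1e-9))
})

test_that("approximate entropy matches the brute-force oracle", {
  expect_equal(approximate_entropy(rep(5, 60)), 0)
  # strictly periodic series has near-zero ApEn
  per <- rep(c(1, 2), 100)
  expect_lt(abs(approximate_entropy(per, m = 2, r = 0.2 * sd(per))), 0.02)

  set.seed(17)
  for (case in 1:3) {
    x <- rnorm(120)
    r <- 0.2 * sd(x)
    for (m in c(1, 2)) {
      expect_equal(approximate_entropy(x, m = m, r = r),
                   apen_oracle(x, m = m, r = r), tolerance = 1e-12)
    }
  }
  expect_error(approximate_entropy(1:3, m = 2, r = 1), "too short")
})

test_that("baseline excludes excursions and tracks drift", {
  expect_equal(baseline_mantel(const_segment(140))$FHRB, 140)

  # two +20 bpm 20-s bumps leave the baseline within 1 bpm
  x <- bump_trace(amp = 20, dur_s = 20, center_s = 300)
  x <- x + bump_trace(amp = 20, dur_s = 20, center_s = 900) - 140
  expect_lt(abs(baseline_mantel(x)$FHRB - 140), 1)

  # linear drift 135 -> 145: baseline mean near the midpoint
  drift <- seq(135, 145, length.out = 2400)
  expect_lt(abs(baseline_mantel(drift)$FHRB - 140), 0.5)
})

test_that("event detection applies the amplitude-duration clauses", {
  base <- rep(140, 2400)
  # +17 bpm for 20 s -> one large acceleration
  ev <- detect_events(bump_trace(amp = 17, dur_s = 20), base)
  expect_equal(ev$large_accels, 1)
  expect_equal(ev$small_accels, 0)

  # +12 bpm for 16 s -> one small acceleration
  ev <- detect_events(bump_trace(amp = 12, dur_s = 16), base)
  expect_equal(ev$small_accels, 1)
  expect_equal(ev$large_accels, 0)

  # -25 bpm for 35 s -> one deceleration (20 bpm / 30 s clause)
  ev <- detect_events(bump_trace(amp = -25, dur_s = 35, thr = 20), base)
  expect_equal(ev$decels, 1)

  # -12 bpm for 65 s -> one deceleration (10 bpm / 60 s clause)
  ev <- detect_events(bump_trace(amp = -12, dur_s = 65, thr = 10), base)
  expect_equal(ev$decels, 1)

  # -15 bpm for 40 s -> no deceleration (neither clause satisfied)
  ev <- detect_events(bump_trace(amp = -15, dur_s = 40, thr = 10), base)
  expect_equal(ev$decels, 0)

  ev <- detect_events(const_segment(), rep(140, 2400))
  expect_equal(unlist(ev), c(small_accels = 0, large_accels = 0, decels = 0))
})

test_that("events injected with margin above thresholds are recovered exactly", {
  base <- rep(140, 2400)
  x <- base
  for (c_s in c(200, 500, 800)) x <- x + bump_trace(amp = 18, dur_s = 20,
                                                    center_s = c_s) - 140
  x <- x + bump_trace(amp = -24, dur_s = 35, center_s = 1050, thr = 20) - 140
  ev <- detect_events(x, base)
  expect_equal(ev$large_accels, 3)
  expect_equal(ev$decels, 1)
})

test_that("min-max scaling learns on training rows and clips test rows", {
  tr <- data.frame(a = c(10, 20, 30), b = c(0, 0.5, 1))
  sc <- fit_feature_scaler(tr)
  out <- apply_feature_scaler(sc, tr)
  expect_equal(out[, "a"], c(0, 0.5, 1))
  expect_equal(out[, "b"], c(0, 0.5, 1))  # already spanning [0,1]: unchanged

  te <- data.frame(a = c(-5, 45), b = c(0.2, 2))
  out_te <- apply_feature_scaler(sc, te)
  expect_equal(out_te[, "a"], c(0, 1))    # clipped
  expect_true(all(out_te >= 0 & out_te <= 1))

  expect_warning(sc2 <- fit_feature_scaler(data.frame(a = c(1, 1), b = 1:2)),
                 "constant")
  expect_equal(apply_feature_scaler(sc2, data.frame(a = c(1, 7), b = 1:2))[, "a"],
               c(0, 0))
})

test_that("the assembled feature vector has the 15 named regressors", {
  fv <- extract_features(const_segment(130))
  expect_named(fv, feature_names())
  expect_equal(unname(fv["FHRB"]), 130)
  expect_equal(unname(fv["STV"]), 0)
  expect_equal(unname(fv["ApEn"]), 0)
})
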