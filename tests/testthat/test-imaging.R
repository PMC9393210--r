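# Signal-to-image encoders: hand-computed examples, algebraic
# invariants, and the 64x64 [0,1] pipeline contract.

test_that("PAA block means and edge cases", {
  expect_equal(paa_downsample(c(1, 1, 2, 2), 2), c(1, 2))
  x <- rnorm(64)
  expect_identical(paa_downsample(x, 64), x)
  expect_true(all(paa_downsample(rep(3, 100), 7) == 3))
  # remainder folds into the last block: 10 -> 3 blocks of 3,3,4
  expect_equal(paa_downsample(1:10, 3), c(2, 5, 8.5))
  expect_error(paa_downsample(1:4, 0), "positive")
})

test_that("Gramian angular fields match the polar-coordinate arithmetic", {
  # x = [1,2,3] -> rescaled [-1,0,1], angles [pi, pi/2, 0]
  g <- gaf(c(1, 2, 3), "summation")
  expect_equal(g[1, 3], cos(pi + 0))        # -1
  expect_equal(g[2, 2], cos(pi / 2 + pi / 2))  # -1
  expect_equal(g[3, 3], 1)
  d <- gaf(c(1, 2, 3), "difference")
  expect_equal(d[1, 3], sin(pi - 0))        # ~0 at the corner
  expect_true(all(abs(diag(d)) < 1e-15))

  set.seed(4)
  x <- rnorm(32)
  gs <- gaf(x, "summation"); gd <- gaf(x, "difference")
  expect_equal(gs, t(gs))                   # GASF symmetric
  expect_equal(gd, -t(gd))                  # GADF antisymmetric
  xt <- 2 * (x - min(x)) / (max(x) - min(x)) - 1
  expect_equal(diag(gs), 2 * xt^2 - 1)      # diagonal identity
  expect_warning(gc_ <- gaf(rep(2, 8), "summation"), "constant")
  expect_equal(unique(as.vector(gc_)), -1)  # all angles pi/2
})

test_that("Markov transition field reproduces hand transition counts", {
  # series [1,1,2,2], 2 bins: transitions 1->1, 1->2, 2->2
  f <- mtf(c(1, 1, 2, 2), n_bins = 2)
  W <- attr(f, "W")
  expect_equal(W, matrix(c(0.5, 0, 0.5, 1), 2, 2))
  expect_equal(f[1, 4], 0.5)                # W[state(1)=1, state(4)=2]
  expect_equal(rowSums(W), c(1, 1))         # row-stochastic

  fc <- mtf(rep(7, 10), n_bins = 4)
  expect_equal(length(unique(as.vector(fc))), 1)  # degenerate: constant field

  set.seed(5)
  x <- rnorm(64)
  f2 <- mtf(x, n_bins = 8)
  expect_equal(rowSums(attr(f2, "W")), rep(1, nrow(attr(f2, "W"))))
  expect_true(all(f2 >= 0 & f2 <= 1))

  # patch aggregation preserves [0,1] and shrinks by m
  f3 <- mtf(rnorm(120), n_bins = 8, patch = 30)
  expect_equal(dim(f3), c(4, 4))
  expect_true(all(f3 >= 0 & f3 <= 1))
})

test_that("recurrence matrices match hand computation and symmetries", {
  r <- recurrence_matrices(c(0, 1, 3), eps = 1.5)
  expect_equal(r$S, matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3))
  expect_equal(r$R, matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3))

  set.seed(6)
  x <- rnorm(40)
  rr <- recurrence_matrices(x)
  expect_equal(rr$S, t(rr$S))
  expect_true(all(diag(rr$S) == 0))
  expect_true(all(diag(rr$R) == 1))
  expect_equal(rr$R, t(rr$R))
  expect_true(all(rr$R %in% c(0, 1)))
  expect_error(recurrence_matrices(x, eps = -1), "non-negative")
})

test_that("scalogram peaks at the scale matching the input frequency", {
  z <- cwt_scalogram(rep(0, 2400))
  expect_true(all(z == 0))

  sc <- cwt_scalogram(sine_segment(0.1))
  freqs <- attr(sc, "freqs")
  target <- which.min(abs(freqs - 0.1))
  # away from the cone-of-influence edges, the per-time argmax scale maps
  # to a pseudo-frequency near 0.1 Hz
  mid <- 600:1800
  argmax <- apply(sc[, mid], 2, which.max)
  expect_lt(median(abs(freqs[argmax] - 0.1)), 0.02)
  expect_equal(round(median(argmax)), target, tolerance = 1)
})

test_that("spectrogram localizes frequency and conserves windowed energy", {
  z <- power_spectrogram(rep(0, 2400))
  expect_true(all(z == 0))

  P <- power_spectrogram(sine_segment(0.25))
  f <- attr(P, "freq")
  amx <- apply(P, 2, which.max)
  expect_true(all(abs(f[amx] - 0.25) < 0.02))

  # Parseval per frame: one-sided power (with doubling) = N * energy of
  # the windowed frame
  set.seed(8)
  x <- rnorm(2400)
  P2 <- power_spectrogram(x)
  nwin <- 120
  w <- as.numeric(signal::hanning(nwin))
  xm <- x - mean(x)
  starts <- seq(1, 2400 - nwin + 1, by = 60)
  dbl <- c(1, rep(2, nrow(P2) - 2), 1)
  for (j in seq(1, length(starts), by = 7)) {
    frame <- xm[starts[j]:(starts[j] + nwin - 1)] * w
    lhs <- sum(P2[, j] * dbl) / nwin
    expect_equal(lhs, sum(frame^2), tolerance = 1e-6)
  }
})

test_that("persistence spectrum counts one increment per frame-frequency pair", {
  H <- persistence_spectrum(sine_segment(0.25))
  P <- power_spectrogram(sine_segment(0.25))
  expect_equal(sum(H), ncol(P) * nrow(P))

  # a stationary sinusoid occupies a persistent hot cell column-wise
  expect_gte(max(H), ncol(P))

  # two tones -> at least two high-count cells in distinct frequency bins
  two <- fhr_segment(140 + 5 * sin(2 * pi * 0.1 * (0:2399) / 2) +
                       5 * sin(2 * pi * 0.6 * (0:2399) / 2))
  H2 <- persistence_spectrum(two)
  hot <- which(H2 >= 0.9 * ncol(P), arr.ind = TRUE)
  expect_gte(length(unique(hot[, 2])), 2)
})

test_that("finalized images are 64x64 in [0,1] and deterministic", {
  expect_warning(z <- finalize_image(matrix(5, 10, 10)), "constant")
  expect_true(all(z == 0))
  expect_equal(dim(z), c(64, 64))

  m <- matrix(runif(64 * 64), 64, 64)
  expect_equal(finalize_image(m), (m - min(m)) / (max(m) - min(m)))

  seg <- sine_segment(0.15)
  for (e in encoder_names()) {
    img <- encode_image(seg, e)
    expect_equal(dim(img), c(64, 64))
    expect_gte(min(img), 0)
    expect_lte(max(img), 1)
  }
  # bit-identical on identical input
  expect_identical(encode_image(seg, "GADF"), encode_image(seg, "GADF"))
  expect_identical(encode_image(seg, "PSP"), encode_image(seg, "PSP"))
})

test_that("stacks assemble distinct encoders in declared order", {
  seg <- sine_segment(0.2)
  st <- encode_stack(seg)
  expect_equal(dim(st), c(64, 64, 3))
  expect_equal(dimnames(st)[[3]], c("GADF", "PS", "PSP"))
  expect_equal(st[, , "PS"], encode_image(seg, "PS"), ignore_attr = TRUE)
  expect_error(encode_stack(seg, c("PS", "PS")), "distinct")
})
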