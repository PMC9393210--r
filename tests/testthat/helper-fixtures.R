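# Shared fixtures: tiny hand-built traces and segments used across the
# unit tests. Everything is generated in code; no data files.

# A clean constant-rate segment (2400 samples).
const_segment <- function(bpm = 140, label = 0L) {
  fhr_segment(rep(bpm, 2400), label = label,
              gestational_week = 36, maternal_age = 30)
}

# Constant trace with a raised-cosine bump (amplitude bpm, supra-threshold
# duration dur_s at the thr level) centred at center_s.
bump_trace <- function(n = 2400, base = 140, amp = 20, dur_s = 20,
                       center_s = 600, thr = 10, fs = 2) {
  x <- rep(base, n)
  c_frac <- thr / abs(amp)
  u0 <- acos(1 - 2 * c_frac) / (2 * pi)
  total_s <- dur_s / (1 - 2 * u0)
  half <- round(total_s * fs / 2)
  idx <- (round(center_s * fs) - half):(round(center_s * fs) + half)
  keep <- idx >= 1 & idx <= n
  u <- (idx[keep] - idx[1]) / (2 * half)
  x[idx[keep]] <- x[idx[keep]] + amp * 0.5 * (1 - cos(2 * pi * u))
  x
}

# A segment carrying a 0.1 Hz (or other) sinusoid on a constant baseline.
sine_segment <- function(freq_hz, amp = 5, base = 140, n = 2400, fs = 2) {
  fhr_segment(base + amp * sin(2 * pi * freq_hz * (seq_len(n) - 1) / fs))
}

# Independent O(N^2) double-loop ApEn oracle (Pincus convention,
# self-matches included, Chebyshev distance).
apen_oracle <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    cnt <- numeric(nt)
    for (i in seq_len(nt)) {
      ci <- 0
      for (j in seq_len(nt)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) ci <- ci + 1
      }
      cnt[i] <- ci / nt
    }
    mean(log(cnt))
  }
  phi(m) - phi(m + 1)
}

# Straightforward per-minute loop oracle for the time-domain indices.
time_domain_oracle <- function(t24) {
  n_min <- length(t24) %/% 24
  stv_j <- delta_j <- ii_j <- numeric(n_min)
  for (j in seq_len(n_min)) {
    mi <- t24[((j - 1) * 24 + 1):(j * 24)]
    ad <- abs(diff(mi))
    stv_j[j] <- mean(ad)
    delta_j[j] <- max(mi) - min(mi)
    ii_j[j] <- if (stv_j[j] > 0) sd(ad) / stv_j[j] else 0
  }
  n_win <- n_min %/% 3
  lti_w <- numeric(n_win)
  for (w in seq_len(n_win)) {
    seg <- t24[((w - 1) * 72 + 1):(w * 72)]
    mm <- numeric(71)
    for (i in 1:71) mm[i] <- sqrt(seg[i]^2 + seg[i + 1]^2)
    lti_w[w] <- IQR(mm)
  }
  list(STV = mean(stv_j), DELTA = mean(delta_j), II = mean(ii_j),
       LTI = mean(lti_w))
}
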