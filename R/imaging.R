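# Signal-to-image encoders: each 20-minute segment becomes a set of
# single-channel 64x64 images in [0,1] for the CNN branch. Pairwise
# encoders (GASF/GADF/MTF/S/R) run on a PAA-downsampled series of length
# 64 and are natively 64x64; time-frequency encoders (CWT, PS, PSP) run on
# the full 2400-sample trace and are min-max normalized then bilinearly
# resized.

#' Encoder names
#' @return Character vector of the eight encoder identifiers.
#' @export
encoder_names <- function() c("CWT", "GASF", "GADF", "MTF", "S", "R", "PS", "PSP")

#' Piecewise aggregate approximation (PAA)
#'
#' Downsamples a series to `target_len` values by averaging contiguous
#' blocks; when the length is not divisible, the trailing remainder is
#' folded into the last block.
#'
#' @param x Numeric series.
#' @param target_len Output length (must be in `1..length(x)`).
#' @return Numeric vector of length `target_len`.
#' @export
#' @examples
#' paa_downsample(c(1, 1, 2, 2), 2)  # 1 2
paa_downsample <- function(x, target_len) {
  n <- length(x)
  if (target_len <= 0) stop("target_len must be positive")
  if (target_len > n) stop("target_len exceeds series length")
  if (target_len == n) return(x)
  block <- n %/% target_len
  edges <- c((0:(target_len - 1)) * block, n)  # last block absorbs remainder
  vapply(seq_len(target_len),
         function(i) mean(x[(edges[i] + 1):edges[i + 1]]), numeric(1))
}

# Rescale to [-1, 1]; constant series maps to all-zero with a warning
# (arccos is then pi/2 everywhere).
.rescale_pm1 <- function(x) {
  rng <- range(x)
  if (rng[2] <= rng[1]) {
    warning("constant series: rescaled to all zeros")
    return(rep(0, length(x)))
  }
  2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
}

#' Gramian angular field (GASF / GADF)
#'
#' The series is min-max rescaled to `[-1, 1]` and mapped to polar angles
#' `phi = arccos(x)`. The summation field is `cos(phi_i + phi_j)`
#' (symmetric); the difference field is `sin(phi_i - phi_j)`
#' (antisymmetric, zero diagonal). Both preserve temporal structure as a
#' bijective pairwise encoding.
#'
#' @param x Numeric series (already downsampled for a native 64x64 image).
#' @param mode `"summation"` or `"difference"`.
#' @return Square numeric matrix with values in `[-1, 1]`.
#' @export
gaf <- function(x, mode = c("summation", "difference")) {
  mode <- match.arg(mode)
  xs <- .rescale_pm1(x)
  xs <- pmin(pmax(xs, -1), 1)
  s <- sqrt(pmax(0, 1 - xs^2))  # sin(arccos(xs))
  if (mode == "summation") {
    outer(xs, xs) - outer(s, s)        # cos(a+b)
  } else {
    outer(s, xs) - outer(xs, s)        # sin(a-b)
  }
}

#' Markov transition field (MTF)
#'
#' The series is partitioned into `n_bins` quantile bins; a row-normalized
#' one-step transition matrix `W` is estimated from successive pairs; the
#' full field is `F[i, j] = W[state(i), state(j)]`, indexed by time so the
#' temporal dimension is preserved; finally non-overlapping `patch x patch`
#' blocks are averaged to reduce the image size. Bins with no outgoing
#' transitions get a uniform row.
#'
#' @param x Numeric series.
#' @param n_bins Number of quantile bins (default 8).
#' @param patch Aggregation patch size `m` (default 1 = no aggregation;
#'   the series is trimmed to a multiple of `patch`).
#' @return Square matrix of transition probabilities in `[0, 1]`, with the
#'   transition matrix attached as attribute `W`.
#' @export
mtf <- function(x, n_bins = 8, patch = 1) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  n <- length(x)
  if (patch > 1) {
    keep <- (n %/% patch) * patch
    x <- x[seq_len(keep)]
    n <- keep
  }
  brk <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  q <- length(brk) - 1L
  if (q < 1L) {  # constant series: one degenerate state
    st <- rep(1L, n); q <- 1L
  } else {
    st <- findInterval(x, brk, rightmost.closed = TRUE, all.inside = TRUE)
  }
  W <- matrix(0, q, q)
  for (i in seq_len(n - 1L)) W[st[i], st[i + 1L]] <- W[st[i], st[i + 1L]] + 1
  rs <- rowSums(W)
  empty <- rs == 0
  W[!empty, ] <- W[!empty, , drop = FALSE] / rs[!empty]
  W[empty, ] <- 1 / q
  f <- W[cbind(rep(st, times = n), rep(st, each = n))]
  f <- matrix(f, n, n)  # f[i, j] = W[st_i, st_j]
  if (patch > 1) {
    np <- n %/% patch
    grp <- rep(seq_len(np), each = patch)
    f <- rowsum(f, grp) / patch
    f <- t(rowsum(t(f), grp) / patch)
  }
  attr(f, "W") <- W
  f
}

#' Recurrence matrices (S and R)
#'
#' `S[i, j] = |x_i - x_j|` is the pairwise distance matrix of the series;
#' `R = S <= eps` is its thresholded binary recurrence plot, marking the
#' times when the trajectory revisits the same region.
#'
#' @param x Numeric series.
#' @param eps Recurrence threshold; default is the 20th percentile of the
#'   off-diagonal distances (scale-adaptive).
#' @return List with `S` (numeric matrix), `R` (0/1 matrix) and the `eps`
#'   used.
#' @export
recurrence_matrices <- function(x, eps = NULL) {
  S <- abs(outer(x, x, "-"))
  if (is.null(eps)) {
    off <- S[upper.tri(S)]
    eps <- as.numeric(stats::quantile(off, 0.2))
  }
  if (eps < 0) stop("recurrence threshold eps must be non-negative")
  R <- (S <= eps) * 1
  list(S = S, R = R, eps = eps)
}

#' Morlet scalogram (continuous wavelet transform magnitude)
#'
#' FFT-based continuous wavelet transform with an analytic Morlet mother
#' wavelet (centre frequency `omega0 = 6` rad), over `n_scales`
#' geometrically spaced scales whose pseudo-frequencies cover
#' `freq_range`. Returns the coefficient magnitudes, scales on the rows
#' (ordered from high to low pseudo-frequency), time on the columns.
#'
#' @param segment An [fhr_segment()] or numeric vector at 2 Hz.
#' @param n_scales Number of scales (default 64).
#' @param freq_range Pseudo-frequency coverage in Hz (default 0.01 to 1).
#' @param omega0 Morlet centre frequency in rad (default 6).
#' @return Matrix of magnitudes with attribute `freqs` (pseudo-frequency
#'   per row, Hz).
#' @export
cwt_scalogram <- function(segment, n_scales = 64, freq_range = c(0.01, 1),
                          omega0 = 6) {
  x <- if (inherits(segment, "fhr_segment")) segment$fhr else as.numeric(segment)
  n <- length(x)
  fs <- fhr_sampling()$fs_hz
  dt <- 1 / fs
  # Morlet pseudo-frequency: f = omega0 / (2 pi s)  (s in seconds)
  freqs <- exp(seq(log(freq_range[2]), log(freq_range[1]),
                   length.out = n_scales))
  scales <- omega0 / (2 * pi * freqs)
  xf <- stats::fft(x - mean(x))
  w <- 2 * pi * fs * c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  out <- matrix(0, n_scales, n)
  for (k in seq_len(n_scales)) {
    s <- scales[k]
    psi <- pi^(-0.25) * exp(-(s * w - omega0)^2 / 2) * (w > 0)
    out[k, ] <- Mod(stats::fft(xf * Conj(psi) * sqrt(s), inverse = TRUE)) / n
  }
  attr(out, "freqs") <- freqs
  out
}

# Short-time Fourier transform with a Hann window; one-sided bins
# including DC and Nyquist so that energy bookkeeping is exact.
.stft <- function(x, nwin, overlap, fs) {
  n <- length(x)
  if (nwin > n) stop("window longer than the signal")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- as.numeric(signal::hanning(nwin))
  nf <- nwin %/% 2 + 1L
  frames <- vapply(starts, function(s) x[s:(s + nwin - 1L)] * w,
                   numeric(nwin))
  X <- stats::mvfft(frames)[seq_len(nf), , drop = FALSE]
  list(S = X, freq = (seq_len(nf) - 1L) * fs / nwin,
       time = (starts - 1L + nwin / 2) / fs, nwin = nwin)
}

#' Power spectrogram
#'
#' Squared magnitude of the short-time Fourier transform of the segment
#' (Hann window, overlapping frames), frequencies on the rows (one-sided,
#' DC to Nyquist), frames ordered in time on the columns.
#'
#' @param segment An [fhr_segment()] or numeric vector at 2 Hz.
#' @param nwin Window length in samples (default 120 = 1 minute).
#' @param overlap Overlap fraction in `[0, 1)` (default 0.5).
#' @return Matrix of power values with attributes `freq` (Hz) and `time`
#'   (s).
#' @export
power_spectrogram <- function(segment, nwin = 120, overlap = 0.5) {
  x <- if (inherits(segment, "fhr_segment")) segment$fhr else as.numeric(segment)
  st <- .stft(x - mean(x), nwin = nwin, overlap = overlap,
              fs = fhr_sampling()$fs_hz)
  P <- Mod(st$S)^2
  attr(P, "freq") <- st$freq
  attr(P, "time") <- st$time
  P
}

#' Persistence spectrum
#'
#' A bivariate occupancy histogram in power-frequency space: for every
#' spectrogram frame and every frequency bin, the 2-D
#' (frequency x dB-power) cell containing that frame's log-power is
#' incremented by one; the image is the sum over all frames, so the hotter
#' a cell the longer that frequency persisted at that power. Power bins on
#' the rows (low dB at the bottom row after finalization), frequency bins
#' on the columns.
#'
#' @param segment An [fhr_segment()] or numeric vector at 2 Hz.
#' @param n_freq_bins,n_power_bins Histogram geometry (defaults 64 x 64).
#' @param nwin,overlap Spectrogram parameters (see [power_spectrogram()]).
#' @return Integer count matrix (`n_power_bins` x `n_freq_bins`); the
#'   total count equals `n_frames * n_spectrogram_freq_bins`.
#' @export
persistence_spectrum <- function(segment, n_freq_bins = 64,
                                 n_power_bins = 64, nwin = 120,
                                 overlap = 0.5) {
  P <- power_spectrogram(segment, nwin = nwin, overlap = overlap)
  f <- attr(P, "freq")
  db <- 10 * log10(P + .Machine$double.xmin)
  fr <- range(f)
  fbin <- findInterval(f, seq(fr[1], fr[2], length.out = n_freq_bins + 1),
                       rightmost.closed = TRUE, all.inside = TRUE)
  dr <- range(db)
  if (dr[2] <= dr[1]) dr <- dr + c(-1, 1)
  pbin <- findInterval(db, seq(dr[1], dr[2], length.out = n_power_bins + 1),
                       rightmost.closed = TRUE, all.inside = TRUE)
  pbin <- matrix(pbin, nrow = nrow(P))
  # one increment per (frame, frequency-bin) pair
  lin <- pbin + (fbin - 1L) * n_power_bins
  counts <- tabulate(as.vector(lin), nbins = n_power_bins * n_freq_bins)
  matrix(as.integer(counts), n_power_bins, n_freq_bins)
}

#' Finalize an image: min-max normalize and resize to 64x64
#'
#' The matrix is min-max mapped to `[0, 1]` (a constant matrix becomes an
#' all-zero image with a warning) and bilinearly resized to
#' `size x size`.
#'
#' @param m Numeric matrix.
#' @param size Target side length (default 64).
#' @return `size x size` matrix with values in `[0, 1]`.
#' @export
finalize_image <- function(m, size = 64) {
  m <- as.matrix(m)
  rng <- range(m)
  if (rng[2] <= rng[1]) {
    warning("constant image: normalized to all zeros")
    m[] <- 0
  } else {
    m <- (m - rng[1]) / (rng[2] - rng[1])
  }
  if (!all(dim(m) == c(size, size)))
    m <- EBImage::resize(m, w = size, h = size)
  pmin(pmax(m, 0), 1)
}

#' Encode a segment with one named encoder
#'
#' Pairwise encoders (GASF, GADF, MTF, S, R) operate on a PAA-downsampled
#' series of length `size` and are natively `size x size`; CWT, PS and PSP
#' run on the full-resolution trace and are resized. All outputs are
#' min-max normalized to `[0, 1]`.
#'
#' @param segment An [fhr_segment()].
#' @param encoder One of [encoder_names()].
#' @param size Image side length (default 64).
#' @return `size x size` matrix in `[0, 1]`.
#' @export
encode_image <- function(segment, encoder, size = 64) {
  encoder <- match.arg(encoder, encoder_names())
  x <- segment$fhr
  m <- switch(encoder,
    CWT  = cwt_scalogram(segment),
    GASF = gaf(paa_downsample(x, size), "summation"),
    GADF = gaf(paa_downsample(x, size), "difference"),
    MTF  = mtf(paa_downsample(x, size), n_bins = 8, patch = 1),
    S    = recurrence_matrices(paa_downsample(x, size))$S,
    R    = recurrence_matrices(paa_downsample(x, size))$R,
    PS   = power_spectrogram(segment),
    PSP  = persistence_spectrum(segment))
  finalize_image(m, size = size)
}

#' Default encoder stack
#'
#' The combination of images found most informative for the CNN branch:
#' the Gramian angular difference field, the power spectrogram and the
#' persistence spectrum.
#'
#' @return Character vector `c("GADF", "PS", "PSP")`.
#' @export
default_encoders <- function() c("GADF", "PS", "PSP")

#' Encode a segment into an image stack
#'
#' @param segment An [fhr_segment()].
#' @param encoders Character vector of distinct encoder names, in the
#'   channel order expected by the model (default [default_encoders()]).
#' @param size Image side length (default 64).
#' @return `size x size x n` array in `[0, 1]` with channel dimnames set
#'   to the encoder names.
#' @export
encode_stack <- function(segment, encoders = default_encoders(), size = 64) {
  if (anyDuplicated(encoders)) stop("encoder names must be distinct")
  imgs <- lapply(encoders, function(e) encode_image(segment, e, size = size))
  arr <- array(unlist(imgs), dim = c(size, size, length(encoders)),
               dimnames = list(NULL, NULL, encoders))
  arr
}
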