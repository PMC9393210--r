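---
title: "Mixed-data classification of fetal heart rate recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-data classification of fetal heart rate recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Antepartum cardiotocography (CTG) records the fetal heart rate (FHR) at
2 Hz, in beats per minute, during non-stress monitoring sessions. Visual
interpretation of these traces suffers from well-documented inter- and
intra-observer variability, and classical computerized indices alone have
not produced a reliable antenatal screen. `fhrfusion` implements a
mixed-data approach to the dichotomous question — healthy versus
pathological fetus — that combines two complementary descriptions of the
same 20-minute FHR segment:

* a panel of **15 quantitative regressors** (classical time-domain
  variability indices, spectral band powers, approximate entropy,
  baseline statistics, event counts, and two maternal covariates), fed to
  a multilayer perceptron (MLP); and
* a configurable stack of **64 × 64 image encodings** of the same signal
  (time-frequency maps and pairwise-structure fields), fed to a
  convolutional network (CNN).

The two branches are fused and trained jointly, so the classifier can
combine interpretable physiology-linked parameters with features the
convolutional branch learns on its own.

Because clinical CTG archives are not freely redistributable, the package
ships a synthetic CTG generator that emulates the statistical structure
of real traces. Every stage of the pipeline — denoising, feature
extraction, imaging, training, evaluation — is exercised and validated on
synthetic data with known ground truth.

## Preprocessing

Raw traces are gappy: transducer displacement and fetal movement cause
dropouts, conventionally stored as zero readings. The cleaning rules are:

* a sample is **valid** iff it is finite and inside 50–220 bpm (zero
  readings therefore always invalid). The bounds are conventional
  physiological FHR limits;
* maximal invalid runs shorter than 15 s (i.e. fewer than 30 samples at
  2 Hz) are filled by **linear interpolation** between the flanking valid
  samples; runs of 15 s or longer are **spliced out**, shortening the
  trace. Runs touching either end of a record have no flanking sample and
  are spliced, never extrapolated;
* the repaired trace is tiled, from offset zero and without overlap, into
  segments of exactly **2400 samples (20 minutes)**; the trailing
  remainder is dropped. A segment with more than 10% interpolated samples
  is rejected as too corrupted. The 10% cap is a conventional CTG-quality
  cut; "excessive corruption" has no standard quantitative definition.

Splicing happens once per record, before tiling; segment boundaries are
therefore defined on the concatenated clean signal. This ordering is a
package decision — either order is defensible, and the alternative
(tiling first) discards slightly more signal around long gaps.

## The 15-regressor panel

All time-domain indices operate on the **T24 interval series**: the 2 Hz
bpm trace is block-averaged over 2.5-s windows (5 samples) and converted
to interbeat intervals in milliseconds, `T = 60000 / bpm`, giving 24
values per minute and 480 per segment. With per-minute blocks `T(i)`,
`i = 1..24`:

* `STV(j) = mean |T(i+1) − T(i)|`, averaged over minutes `j` — short-term
  variability (ms);
* `DELTA(j) = max T − min T` per minute, averaged — the minute range (ms);
* `II(j) = sd(|T(i+1) − T(i)|) / STV(j)`, averaged — the interval index
  (unitless; defined as 0 for a minute with zero STV);
* `LTI` — long-term irregularity: the interquartile range of
  `m(i) = sqrt(T(i)² + T(i+1)²)` over non-overlapping 3-minute windows,
  averaged over windows (incomplete trailing windows are dropped).

These are the classical Arduini/de-Haan-family definitions used
throughout computerized CTG work.

Spectral powers are computed on the 2 Hz interval signal in ms (not bpm;
the millisecond scale is the convention for these indices), with Welch's
method: 2-minute Hann windows, 50% overlap, per-window linear detrend.
Band powers are integrated over the fetal HRV bands LF 0.03–0.15 Hz, MF
0.15–0.5 Hz ("movement frequency"), HF 0.5–1.0 Hz, and summarized by the
ratio `LF/(MF+HF)` (reported as `NA` when the denominator is zero — never
as infinity). The 2 Hz sampling makes the full HF band observable
(Nyquist 1 Hz).

Approximate entropy uses the Pincus conventions: templates of length
`m = 2`, tolerance `r = 0.2 × sd` of the segment's T24 series, Chebyshev
distance, self-matches included. Both `m` and the `r` factor are exposed
as configuration. The implementation is an O(N²) vectorized computation
and is tested for exact (1e-12) agreement against an independent
double-loop reference.

The baseline is a simplified Mantel-style estimate: a 2-minute moving
average, iteratively re-fitted after replacing samples deviating more
than 10 bpm from the current estimate, until the estimate moves less than
0.1 bpm or 10 iterations. This captures the excursion-trimming character
of clinical baseline algorithms without reproducing any proprietary
variant. `FHRB` is the mean baseline over the segment.

Events are deviations from that baseline, with amplitude–duration
clauses (strict inequalities, durations measured as contiguous time
beyond the deviation threshold):

* small acceleration: > 10 bpm and < 15 bpm peak, sustained ≥ 15 s;
* large acceleration: > 15 bpm peak, sustained ≥ 15 s (an event meeting
  the large criterion is not also counted as small);
* deceleration: > 20 bpm below baseline for ≥ 30 s, or > 10 bpm below
  baseline for ≥ 60 s; each run is counted once.

The panel is completed by gestational week and maternal age, and min-max
scaled to [0, 1]. Scaling statistics are always learned on the training
partition only and reused for test rows, with out-of-range test values
clipped to [0, 1]; this avoids test-set leakage through the
normalization.

## Image encodings

Eight encoders turn a segment into single-channel 64 × 64 images in
[0, 1]:

| name | content |
|------|---------|
| CWT  | Morlet scalogram (wavelet magnitude over 64 geometric scales, pseudo-frequencies 0.01–1 Hz) |
| GASF / GADF | Gramian angular summation / difference fields of the polar-encoded series |
| MTF  | Markov transition field over 8 quantile bins |
| S / R | pairwise distance matrix and its thresholded recurrence plot |
| PS   | power spectrogram, `|STFT|²` with 1-minute Hann frames, 50% overlap |
| PSP  | persistence spectrum: 64 × 64 occupancy histogram in (frequency, dB-power) space |

Design choices worth noting:

* the pairwise encoders (GASF, GADF, MTF, S, R) operate on a
  piecewise-aggregate (PAA) downsampling of the segment to 64 points and
  are therefore natively 64 × 64. Building a 2400 × 2400 field only to
  shrink it to 64 × 64 wastes three orders of magnitude of computation
  for no information gain at the target resolution. The long-series MTF
  path (full series, 30 × 30 patch aggregation, then resize) remains
  implemented and tested;
* the recurrence threshold ε defaults to the 20th percentile of the
  off-diagonal distances, per segment, making R scale-adaptive; S is kept
  unthresholded as its own image;
* a constant series or constant image (degenerate min-max) maps to an
  all-zero image with a warning rather than an error, so a pathological
  segment cannot crash a batch run;
* time-frequency images are min-max normalized then bilinearly resized to
  64 × 64; all encoders are deterministic, so identical input yields
  bit-identical images;
* the default stack is **(GADF, PS, PSP)** — the image combination found
  most informative for this classification task; any subset and order of
  the eight encoders can be configured, and the CNN input depth follows
  the stack size.

The Morlet wavelet (centre frequency 6 rad), the STFT window (120
samples), the MTF bin count (8) and the RP threshold rule are package
defaults, exposed as configuration; no claim is made that they match any
particular clinical software's internals.

## The classifier

The MLP branch is 15 → 500 → 250 → 150 → 50 → 2 with rectifier
activations and a softmax output; dropout 0.4 follows hidden layers 1, 2
and 4; hidden layer 3 carries L1 = 1e-5 and L2 = 1e-4 penalties. The CNN
branch takes the 64 × 64 × n stack and applies conv(16, 5 × 5, no
padding) → ReLU → batch norm → max-pool 2 × 2 → conv(32, 5 × 5) → ReLU →
batch norm → max-pool → dropout 0.8 → flatten (13·13·32 = 5408) → dense
64 → ReLU → batch norm → dropout 0.8 → dense 16 → ReLU → dense 2 →
softmax. The combined model concatenates the two branches' terminal
2-unit softmax outputs (4 fusion inputs) and applies dense 128 → ReLU →
dense 2 → softmax.

Fusing softmax outputs rather than penultimate features is the literal
reading of "the branch outputs are concatenated"; since the alternative
(50 + 16 = 66 penultimate units) is also a reasonable reading, it is
available via `combined_spec(fusion = "penultimate")`. The default stays
with the literal reading.

Multi-image input is realized as channel stacking: the first convolution
kernels are 5 × 5 × n. Training uses Adam (learning rate 1e-4, per-epoch
decay parameter 1e-4/200 applied as `lr/(1 + decay·epoch)`),
cross-entropy on the 2-way softmax (identical to binary cross-entropy for
two classes), minibatches of 32, a stratified 10% validation split of
the training data, and early stopping with patience 2 on validation
loss with restoration of the best-epoch weights. All of these are
configuration fields; the batch size and validation fraction are package
choices where no established convention exists.

The network engine itself (dense, convolution, batch normalization,
max-pooling, dropout, softmax layers; Adam; early stopping) is
implemented in the package — R has no established deep-learning runtime
in this dependency set — with the convolution's im2col gather and
col2im scatter in compiled code. Every layer's backward pass is verified
against finite differences in the development tests, and training is
bit-for-bit reproducible under a fixed seed.

## Evaluation protocol

The positive class is *pathological*. From a confusion matrix the
package reports ACC, TPR (sensitivity), TNR (specificity), PPV
(precision), NPV, FPR, FNR and FDR — with zero-denominator cells
reported as undefined (`NA`), never as 0 — plus the trapezoidal AUC of
the positive-class scores. NPV is `TN/(TN+FN)`: the only definition
consistent with the published values this panel is checked against.

The repeated protocol performs one stratified 80/20 split, fixes the test
set, and retrains the model `repetitions` times (30 by default) with
distinct seeds, reporting per-run accuracies and mean metrics. Model
comparison is a two-sample t-test on per-run accuracies — Welch's test by
default, with a pooled-variance switch — at significance level 0.01. If
both accuracy vectors are constant, the p-value is defined as 1 for equal
means and 0 otherwise.

## The synthetic generator

A generated record is

```
FHR(t) = baseline(t) + band-limited noise(t) + events(t), plus gaps
```

* **baseline**: a per-record level drawn from N(140, 8) bpm plus a
  smooth two-component sinusoidal drift of about ±3 bpm over tens of
  minutes;
* **variability**: three independent Gaussian noise components,
  FFT-filtered to the LF/MF/HF bands and scaled to configured powers
  (healthy default 9 / 2 / 0.8 bpm²);
* **events**: raised-cosine bumps and dips. The shape makes
  supra-threshold duration analytic, so the generator can place an event
  whose duration *at the 10 bpm detection threshold* is exactly the
  configured value — which is what makes exact count-recovery tests
  possible. Healthy defaults: 3 accelerations and 0.3 decelerations per
  20 minutes, with truncated-normal amplitudes and durations;
* **gaps**: Poisson-count dropouts with log-normal durations (median
  6 s), so most gaps are interpolated and a minority trigger splicing;
* **metadata**: gestational week uniform on 32–40 weeks, maternal age
  N(31, 5) truncated to 18–45 years, identical across classes so the
  metadata carries no label signal by default.

The pathological class differs by configured contrast factors:
variability powers × 0.5, acceleration rate × 0.25, deceleration rate
× 3. These contrasts point in the clinically expected directions
(reduced variability and reactivity, more decelerations) and produce
classes that a trained model separates far above chance while a
label-permuted or zero-contrast control does not.

What the generator does **not** emulate: true fetal cardiac dynamics
(no mechanistic model), pathology-specific signatures (IUGR vs diabetes
vs malformation), long-range nonstationarity across a full exam, device
artifacts other than dropouts, or any correlation between metadata and
class. Passing tests on synthetic data therefore demonstrate that the
pipeline is implemented correctly and can learn a planted contrast; they
do not certify clinical performance on real populations, and the
published clinical-scale accuracies are explicitly not reproduction
targets for this package.

## Scaled-down study sizes and numerical choices

The package's own validation runs at desk scale, with sizes chosen to
keep the full suite inside a normal CI budget while leaving the
conclusions qualitative rather than marginal:

* end-to-end learning check: 400 records per class (one segment each),
  80/20 split, combined model; expected held-out accuracy well above
  0.75, against a label-permutation null and a zero-contrast control
  near 0.5;
* the scaled runs train with learning rate 1e-3 and at most 20 epochs:
  a desk-scale run has roughly fifty times fewer gradient steps per
  epoch-budget than a clinical-scale one, and the larger step size
  compensates; the clinical-scale default (1e-4) remains the package
  default in `training_config()`;
* property tests (STV class ordering, band-power monotonicity) use 100
  records per class; oracle tests use series of length 120–500.

Numerical conventions: batch-norm uses momentum 0.9 and eps 1e-5;
Adam uses the standard (0.9, 0.999, 1e-7) constants; weight
initialization is He-scaled Gaussian; max-pool gradient ties resolve to
the first maximal corner; the label-permutation null of a
nearly-separable dataset is *not* guaranteed to sit at 0.5 — a model
trained on permuted labels of clustered data assigns whole clusters to
effectively random labels, so its accuracy distribution is broad — which
is why the learning check compares against the measured null rather than
assuming 0.5, and uses the zero-contrast control for the chance-level
comparison.

## Known limitations

* The event detector counts a merged run of two overlapping excursions
  as a single event; the generator's recovery guarantees therefore hold
  for events separated in time, which the recovery tests enforce.
* The Mantel-style baseline is a simplification; on traces whose
  excursions occupy most of the record the iterative trimming can bias
  the baseline toward the majority state.
* The CNN branch at desk scale is deliberately under-trained (heavy
  dropout, few epochs); its standalone accuracy on synthetic data is not
  meaningful, and the combined model's performance is typically carried
  by the feature branch — consistent with the relative branch accuracies
  reported in the clinical-scale literature.
* Training the combined model on a single CPU costs roughly 10 s per
  epoch at 640 training segments; the repeated 30-run protocol at that
  size is therefore an hours-scale computation and is exercised in tests
  at reduced repetition counts.
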