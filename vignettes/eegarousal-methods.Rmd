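---
title: "Detecting sleep arousals from single-lead EEG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep arousals from single-lead EEG: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A sleep arousal is an abrupt shift of the EEG toward alpha/theta or
faster rhythms, lasting at least 3 s after at least 10 s of stable
sleep.  Counting arousals is central to scoring sleep quality, but
manual scoring of overnight polysomnograms is slow and inter-rater
agreement is poor.  `eegarousal` implements an automatic detector that
needs only a single central EEG derivation (C3-M2) sampled at 200 Hz: it
scores every non-overlapping 30-s window (6000 samples) as *normal* or
*arousal* by stacking four base classifiers under a logistic-regression
meta-classifier.

The pipeline is:

1. **Preprocessing** — low-pass filtering to the 0–40 Hz EEG band
   (removing 60 Hz powerline contamination), discarding the first and
   last hour of each record, cutting the rest into 30-s segments, and
   deriving one Boolean label per segment from the per-sample
   annotations.
2. **Features** — a 29 x 8 band-power matrix from multitaper spectral
   estimates (frequency view), and a 1 x 42 vector of expert statistics
   (time + frequency view).
3. **Base classifiers** — a 1D CNN on the raw waveform, a bidirectional
   LSTM on the band-power sequence, a random forest on the expert
   vector, and a pre-merged CNN+LSTM network.
4. **Stacking** — logistic regression on the four probability pairs,
   deciding *arousal* when the posterior exceeds 0.5.

## Preprocessing choices

The filter is specified as order 127 with passband/stopband edges at
40/42 Hz.  A 127th-order IIR Butterworth filter is numerically
pathological (pole clustering makes the transfer function unstable in
double precision), so the package's default realization is a
linear-phase FIR filter of the stated order designed by least squares to
the stated edges: 128 symmetric taps, DC gain 1 within 1%, and more than
30 dB of attenuation at 60 Hz (about 50 dB in the shipped design).  A
conventional low-order Butterworth cascade applied forward–backward is
available as `filter_spec(realization = "iir")`.  FIR filtering
compensates the 63.5-sample group delay by shifting 64 samples with
edge-replicated padding, so the per-sample labels stay aligned.

Segment labeling is not fully determined by the source material: we mark
a segment positive iff it contains a contiguous arousal run of at least
3 s (600 samples), the AASM minimum event duration.  Runs straddling a
window boundary count only their in-window portion.  Both the threshold
and the window are configurable (`segment_record`, `label_segment`).

## Multitaper band powers

Each segment is analyzed every 2 s (400 samples) with 50% overlap,
giving 29 frames.  Each frame is tapered with the 8 most concentrated
Slepian (DPSS) sequences of length 400 and the squared DFT magnitudes
are averaged *unweighted* across tapers — no Thomson adaptive weights,
matching the plain average in the source model.  Design details:

* **Time-bandwidth product.** Only the taper count (8) and length (400)
  are prescribed.  We default to NW = 4.5 so that the classical
  K = 2NW − 1 rule gives exactly 8 well-concentrated tapers; the
  smallest concentration eigenvalue of the shipped bank is 0.93.  NW is
  exposed in `compute_dpss()`.
* **One-sided scaling.** 201 bins spaced 0.5 Hz; interior bins are
  doubled, DC and the 100 Hz window bin are not.  With unit-energy
  tapers the 201 bins then sum to the frame variance, which makes the
  white-noise Parseval test exact in expectation.
* **No demeaning.** The taper transform is applied literally, so the DC
  bin carries the frame mean.  Band integrals for delta and full start
  at the DC bin, which is therefore part of the documented contract.
* **Quadrature.** Band powers integrate the PSD over the documented
  1-based bin ranges (delta 1–9, theta 10–17, alpha 18–25, beta 30–61,
  full 1–81) by composite Simpson.  Theta, alpha and beta leave an odd
  interval count, so the final three intervals use the 3/8 rule; the
  rule is exact for constants, which the tests exploit.
* **Ratios.** delta/theta, theta/alpha, delta/alpha with the convention
  0/0 → 0 and x/0 → capped at 1e6 (configurable).  Band-limited noise
  keeps denominators strictly positive in practice; the cap only guards
  degenerate inputs such as all-zero segments.

## Expert features

The 42-entry vector is: mean numerical gradient, kurtosis, Hjorth
activity/mobility/complexity, skewness (time domain); then min, mean,
standard deviation and 95th percentile of the eight band-matrix columns,
plus the kurtosis of the four sub-band columns (frequency domain).
Notable conventions, implemented literally from the source equations:

* Kurtosis and skewness standardize a 1/N central moment by the
  (N−1)-denominator standard deviation.  The Gaussian large-sample limit
  is still 3 (resp. 0); a `textbook = TRUE` flag gives the all-1/N
  estimator.
* The time-domain list is exactly the six features above: the source
  text also mentions mean/max/min, but the printed per-feature counts
  sum to 42 only without them, and the 42 total is stated twice.
* The four column-kurtoses are taken over delta, theta, alpha and beta —
  the only four sub-bands the band table defines (the text's "sigma
  band" has no printed bin range to implement).
* The numerical gradient uses central differences with one-sided ends;
  the 95th percentile interpolates linearly between order statistics
  (type-7 quantile).

## Base classifiers

The CNN consumes the per-segment z-scored 6000-sample waveform through
four convolution blocks (two valid ReLU convolutions each, kernel
lengths 50/30/10/2, channel widths 20/20, 20/24, 12/12, 12/12, each
followed by a length-2 max-pool), global average pooling to a 12-vector,
and a softmax dense pair.  `build_cnn()` reports a per-layer parameter
census and output-shape trace; both are asserted against the published
architecture tables in the tests.  Two printed counts (the fifth and
sixth convolutions) are inconsistent with their own stated filter sizes
and output shapes; the implementation follows the shapes and documents
the corrected counts (2892 and 1452).

The RNN consumes the 29 x 8 band matrix as a sequence: a bidirectional
LSTM with 20 hidden units per direction (concatenated to 40), a
unidirectional LSTM of 10 keeping the last state, a dense ReLU layer of
32 (the embedding tap), and a softmax pair.  Band powers span decades,
so the RNN input is log-transformed and z-scored per column with
training-set statistics stored in the model.

The random forest consumes the 42 expert features: 500 trees, sqrt
features per split, fully grown, seeded and single-threaded so the same
seed reproduces the forest exactly.

The pre-merge network concatenates the CNN's 12-dim and the RNN's 32-dim
embeddings into a 44-vector under a softmax head.  What follows the
44-vector is not specified in the source; a single dense softmax layer
is the minimal choice and is what we use.  That head is a linear
classifier on the concatenated embeddings, so it starts from zero
weights (as logistic regression does): with informative trunks a random
initial projection is itself strongly class-correlated with arbitrary
sign, and a short head training could otherwise keep the wrong sign.
Trunks initialize from the
trained CNN/RNN; by default the merged network fine-tunes end to end,
and a `freeze_trunks` flag trains only the head on cached embeddings
(the benchmark profile below uses the flag, trading a possible small
accuracy gain for an order-of-magnitude shorter merged training).

Training hyperparameters are unstated in the source; the package
defaults are Adam (1e-3), batch 64, at most 30 epochs with early
stopping on a 15% validation split (patience 5), cross-entropy loss, all
seeded.  Weight initialization is Glorot-uniform; LSTM forget-gate
biases start at 1.  The convolution forward/backward passes run through
single-precision BLAS kernels; all bookkeeping is double precision, and
training is bit-deterministic given the seed.

## Stacking

The meta input is p = (1, p1, ..., p8): an intercept plus the
(normal, arousal) probability pairs of CNN, RNN, forest and pre-merge.
`fit_meta` minimizes the mean cross-entropy by gradient descent from
beta = 0 with Armijo backtracking (initial step 0.1, tolerance 1e-8 on
the gradient infinity norm, at most 1e5 iterations, no regularization).
Because each pair sums to one next to an intercept column the design is
rank-deficient; gradient descent still converges to a minimum-cost
point, which is all the 0.5-threshold decision needs, and the tests also
verify agreement with IRLS on full-rank problems.  The decision rule is
strict: arousal only when the posterior exceeds 0.5.

How the original meta-classifier obtained its training inputs is not
stated.  In-sample stacking risks leaking the sub-models' training fit,
while full 5-fold out-of-fold stacking retrains every network five
times.  The package implements three protocols (`meta$protocol`):
`"holdout"` (default — a record-disjoint 20% of the training records is
reserved for the meta-classifier), `"insample"`, and `"oof"` (k-fold
out-of-fold, practical with the forest but expensive with the
networks).  Holdout keeps the leakage protection at one extra training
run of nothing.

## Evaluation

Accuracy, sensitivity, specificity and precision follow their
confusion-matrix definitions; AUROC is computed by the midrank
Mann–Whitney statistic, which equals trapezoidal integration of the ROC
curve and handles ties so that AUROC(s) + AUROC(−s) = 1.
Cross-validation assigns whole records to folds, never segments, to
prevent within-subject leakage — the split granularity is our choice,
as the source does not state its own.

## The synthetic generator

Real overnight polysomnograms are multi-gigabyte and cannot ship with a
package, so every stage is exercised on synthetic records with known
ground truth.  A record is the sum of

* band-limited Gaussian noise in delta (0.5–4 Hz, weight 1.0), theta
  (4–8, 0.5), alpha (8–12, 0.35) and beta (14–30, 0.2), produced by
  zero-phase spectral shaping of white noise,
* a broadband noise floor (0.1),
* a pure 60 Hz powerline sinusoid (amplitude 0.5, random phase), and
* arousal events: spans of 3–15 s in which alpha/beta amplitude is
  multiplied by `arousal_band_shift` (default 3), realized by gating an
  independent alpha/beta process scaled so powers add to the target.
  Events are placed by a Poisson candidate process; candidates that
  overlap or start within 10 s of the previous event are rejected,
  mirroring the 10-s stable-sleep requirement.  Labels are 1 exactly on
  the event spans.

The candidate rate default (59/h) was calibrated once, by simulation,
so that the default segment-level prevalence is about 40% — the class
balance of the real dataset the detector was designed for.  Amplitudes
are unitless; every pipeline stage is amplitude-scale covariant except
the deliberately scale-free statistics.

What the generator does **not** emulate: sleep-stage architecture,
artifacts (movement, electrode pops), spindles/K-complexes,
nonstationary background drift, or realistic arousal morphology beyond
the spectral-shift definition.  Tests passing on this data therefore
demonstrate that the machinery is correct and that the detector learns
the spectral signature it was built around — not that it reaches any
particular performance on clinical recordings.

## The synthetic benchmark

`synthetic_benchmark(seed)` is the package's reference experiment: 9
records of 4 h (2160 segments after edge discard, ~40% positive), 2
records held out for testing, holdout stacking on the rest.  Problem
sizes and the reduced-epoch profile (CNN 2 epochs at batch 32, RNN 12
epochs, merged head 8 epochs on frozen trunks, forest at its 500-tree
default) are the package's chosen benchmark conditions for a single
CPU; on this data the networks converge within those budgets, and all
five AUROCs come out well above 0.9.  `scripts/acceptance.R` runs
exactly this benchmark and writes the resulting metrics as JSON.

## Known limitations

* The detector's time resolution is one 30-s window.
* The pre-merge head after the 44-vector, the segment-label rule, the
  time-bandwidth product, all training hyperparameters and the stacking
  protocol are design choices documented above, not prescriptions from
  the source material.
* Ratio features are capped rather than infinite for zero denominators.
* The WFDB reader/writer covers the format-16 single-file dialect used
  by the CinC 2018 polysomnography records, not the full WFDB standard.
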