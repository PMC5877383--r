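---
title: "Feature optimization for sEMG interfaces: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature optimization for sEMG interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgopt)
```

`semgopt` implements the offline workflow of a four-motion myoelectric
interface — preprocessing, a 42-feature bank, separability-based feature
and channel selection, classifier evaluation — and a discrete-time
simulator of the online control paradigms such interfaces use. This
vignette records the models, the parameter defaults and their units, the
conventions adopted where the field's literature names a method without
fully specifying it, and what the bundled synthetic generator can and
cannot tell you about real recordings.

## Signal model and segmentation

A recording is a samples × channels matrix at a sampling rate `fs`
(default 1000 Hz, a common rate for surface EMG whose useful band ends
near 450 Hz). Trials follow the cue-based protocol: a 1.5 s task split
into a 0.25 s onset transient, a 1 s steady execution period and a 0.25 s
offset. Features for training are extracted only from the execution
period, where the contraction is approximately stationary.

Windowing conventions are fixed once and used everywhere:

* sample indexing is 0-based and windows are half-open `[start, end)`;
* window length and stride in samples are `floor(length_s * fs)` and
  `floor(win * (1 - overlap))`, stride at least 1;
* trailing samples that do not fill a window are dropped — so a 1 s
  execution period yields exactly 4 disjoint 250 ms windows, or 8 at
  125 ms, and a 1 s stream with a 125 ms window at 20 % overlap yields
  `floor((1000 - 125)/100) + 1 = 9` windows.

Disjoint segmentation is the training convention; overlapped segmentation
(default 20 % overlap) mimics the sliding real-time analysis.

## Preprocessing

**Filtering.** The conditioning chain is a 10–450 Hz Butterworth band-pass
of 16 poles plus a power-line notch. Two implementation choices matter:

* A 16-pole band-pass expressed as a single transfer function is
  numerically unstable in double precision (its polynomial coefficients
  span too many orders of magnitude), so the band-pass is realized as an
  order-8 high-pass cascaded with an order-8 low-pass — the same 16-pole
  magnitude response, stable to evaluate.
* All filters are applied forward–backward (zero phase) so time-domain
  features downstream are not distorted by phase lag, with reflective end
  padding (up to 1000 samples) to suppress the start-up transients that
  plain forward–backward filtering leaves at the edges.

The notch is an order-4 elliptic band-stop at 50 ± 2 Hz (0.1 dB pass
ripple, 40 dB stop attenuation); harmonics (default up to 200 Hz) get
order-2 Butterworth band-stops of the same half-width. These defaults
attenuate a pure 50 Hz tone by more than 50 dB while costing less than
0.2 dB at 100 Hz. The harmonic count is configurable because the
literature typically says only "50 Hz and its harmonics".

**ICA.** Artifact rejection uses a symmetric fixed-point ICA with tanh
contrast on whitened channels (the standard FastICA iteration), a fixed
seed for the random orthogonal start, and a pluggable rejection rule. The
default rule rejects components with more than 60 % of spectral power
below 10 Hz — targeting baseline drift and motion artifacts — because
published pipelines rarely state their rejection criterion; supplying a
function `(sources, fs) -> indices` overrides it. Rejecting nothing
reconstructs the input to numerical tolerance, and non-convergence after
500 iterations is an error (reported with the iteration count), not a
silent fallback.

**MSPCA.** Multiscale PCA decomposes each channel with a wavelet
transform, runs PCA on the coefficient covariance of each scale
separately, retains the leading components, and reconstructs. Defaults
follow the common convention: DB4 wavelet, 5 levels, and the Kaiser rule
(retain eigenvalues above the scale's mean eigenvalue). `pc_rule = "all"`
is an exact round trip, which the tests use as the identity check.

**SNR.** `compute_snr()` reports `10 log10(A_m² / A_r²)` with `A_m`, `A_r`
the maximum windowed RMS (default 0.25 s windows) of an active and a rest
segment.

## The feature bank

The per-channel bank has 42 dimensions; C channels cascade to 42·C. The
literature lists these features by name without printing formulas, so the
package adopts the standard Phinyomark-convention definitions, documented
per feature in `?extract_time_features` and friends. Conventions chosen
where names are ambiguous:

* **MMAV1/MMAV2 weights**: weight 1 on the central 50 % of the window and
  0.5 elsewhere (MMAV1); piecewise-linear ramps `4i/N` and `4(N−i)/N` on
  the outer quarters (MMAV2).
* **Thresholds**: the two ZC deadbands default to {0, 0.05}·RMS, the five
  WAMP thresholds to {0.05, 0.1, 0.2, 0.3, 0.4}·RMS, and the SSC threshold
  to 0, all per window. Expressing thresholds as fractions of the window
  RMS makes the count features gain-invariant (electrode gain is
  arbitrary); they are configurable because threshold choice is known to
  decide which WAMP variants survive selection.
* **HEMG**: 6 equal-width bins spanning ±3 SD around the window mean;
  samples outside the range are clamped into the edge bins so counts
  always sum to the window length. A constant window puts all samples in
  a central bin.
* **AR**: order-4 Burg estimation (stable on short windows); a constant
  window is an error rather than a fabricated value.
* **MDF/MNF**: Welch PSD (Hamming, 256-sample segments capped at the
  window length, 50 % overlap); MDF is the first bin at which the
  cumulative PSD reaches half the total, MNF the PSD-weighted mean
  frequency.
* **STFT scalar**: the bank reserves a single dimension for the short-time
  Fourier descriptor, reduced here to the mean of the Welch PSD.
* **Wavelet sub-bands**: 6-level DB4 DWT giving 7 sub-bands D1..D6, A6;
  APWC is the mean squared coefficient and SDWC the coefficient standard
  deviation per band. The DWT uses periodized boundaries, which keeps the
  transform orthogonal: windows are zero-padded to the next multiple of
  2^6 (energy-neutral), so band coefficient counts times APWC sum exactly
  to the window energy (Parseval), a property the tests assert. At 125 ms
  = 125 samples, D6 and A6 hold only 2 coefficients each — spread
  estimates there are noisy, which is inherent to a 6-level decomposition
  of so short a window and not corrected for.

## Separability criteria

**EC.** Per feature, per-class variances are normalized to sum to one and
scored by Shannon entropy, `J = −Σ V_k ln V_k` with `0·ln 0 := 0`, bounded
by `[0, ln n]`. The package ranks **ascending** J: a feature whose variance
is concentrated in few classes (low entropy) is the informative one. The
source literature's prose on the direction is internally inconsistent, but
its tabulated selections list ascending values (best ≈ 0.23 for a
two-channel aggregate), which fixes the interpretation adopted here. A
feature with zero variance in every class carries no information and is
assigned the maximum `ln n`.

**FD.** `D²(a,b)` is the mean squared difference over **all |a|·|b|
ordered cross pairs** (including equal-index pairs — they are different
trials), and the within-class terms average **all distinct unordered
pairs**, which collapses to twice the sample variance. The convention is
fixed by hand-enumerated oracle values in the tests ({0,1} vs {3,4} gives
9.5/(1+1) = 4.75). Multi-class scores decompose one-versus-all and average
the n binary ratios; two-class inputs reduce to the plain binary ratio.
Classes with zero within-class spread yield an `Inf` sentinel ranked
first, with a warning — not an epsilon fudge, since downstream code may
legitimately want to catch degenerate features.

**RFE.** The margin criterion "loss of `‖w‖²` when feature i's component
is dropped" equals `w_i²`, so the implementation eliminates the smallest
summed squared weight across the one-versus-all linear machines each
round. Features are standardized first (weights are not comparable across
raw scales). A linear kernel is used inside RFE even though final
classification uses RBF — the weight vector is only explicit for linear
machines, the standard SVM-RFE practice. The tests verify the elimination
order against an independent oracle that retrains via the dual quadratic
program (`kernlab::ipop`) and recursively eliminates by the same criterion
definition.

Ties in any ranking break by canonical feature-name order, so results are
reproducible across platforms.

**Aggregation.** Optimal-feature-number sweeps walk the ranking from 1 to
d features, cross-validating each prefix; the OFN is the arg-max, smallest
size on ties. Cross-subject/channel aggregation min–max normalizes each
report's values to [0, 1], averages across subjects within a channel, and
sums across channels (EC/FD); for RFE it counts how often each feature
appears in a report's top k, so nine subjects × two channels bound the
count at 18. Channel ranking cross-validates all 6 class pairs per channel
on the full bank and orders channels by mean pairwise accuracy, keeping
the top 2 by default (a two-channel montage is the practical wearable
configuration).

## Classifiers

Defaults follow the configurations common in four-motion sEMG work: kNN
with k = 6; a single-hidden-layer network with `2n` logistic hidden units
and a softmax output over the 4 classes, trained by backpropagation
(`nnet`) with weight decay 5e-4 and 200 iterations — `nnet` has no
validation-based early stopping, so decay plays the regularizing role;
a 30-tree random forest with `mtry = round(log2(d))` (non-integer values
rounded to nearest, minimum 1); and an RBF SVM decomposed one-versus-all,
predicting the class with the largest decision value. SVM hyperparameters
default to the LIBSVM conventions C = 1, γ = 1/d; `tune = TRUE` enables a
small inner 3-fold grid search (C ∈ {0.1, 1, 10}, γ ∈ {0.1, 1, 10}/d),
off by default because a nested grid inside every fold of a 42-step OFN
sweep multiplies runtime by two orders of magnitude for little gain on
separable data.

Cross-validation is stratified (plain random folds can starve a class at
small trial counts), 10-fold by default and 5-fold for the network. Fold
assignment and all stochastic backends derive from one seed argument, so
repeated runs are identical. Reported metrics: overall accuracy (%),
macro-averaged F-score `2TP/(2TP + FP + FN)`, and a confusion matrix with
rows (true classes) normalized to 100 %.

## The synthetic generator

`generate_semg()` emulates the statistical structure that the pipeline
exploits, not the physiology that produces it. Each trial is
envelope-modulated (0.25 s linear onset ramp, 1 s plateau, 0.25 s offset)
band-limited Gaussian noise: rest is a low-gain broadband floor
(gain 0.06), fist-making is strongest at low frequencies (10–105 Hz),
wrist flexion in the 105–195 Hz band, wrist extension mid-band
(40–250 Hz), matching the qualitative class spectra reported for forearm
recordings. A class × channel gain matrix couples each movement most
strongly into one of the four electrode sites (APL, ECR, ECU, FCU), white
measurement noise (SD 0.05) and 50 Hz interference (amplitude 0.1) are
added before any filtering, and everything is deterministic per seed.
Trials per class default to 40, so a 250 ms disjoint segmentation of the
execution periods yields 160 windows per class.

What it does **not** emulate: motor-unit action potentials and their
recruitment/firing statistics, amplitude non-stationarity within the
plateau, fatigue drift across trials, electrode lift-off or impedance
changes, and cross-talk that varies with posture. Consequently the
end-to-end tests passing at ≥ 95 % accuracy demonstrate that the pipeline
is implemented correctly and can exploit class-dependent spectra and
gains; they do not predict accuracy on human recordings, where class
overlap is far larger and the same pipeline's published accuracies sit in
the mid-90s for selected channels.

`generate_planted_features()` bypasses signals entirely and draws a
feature matrix directly: planted columns shift both their class means
(`effect_size` SD per class step) and class SDs (factor
`1 + effect_size·k/2`), so variance-based (EC) and distance-based (FD,
RFE) criteria can each detect them; `effect_size = 0` makes all features
exchangeable, the null case.

## Control simulator

Commands map as: fist → forward, rest → backward, wrist extension →
clockwise, wrist flexion → anti-clockwise (paradigms 2 and 3); the state
machine (paradigm 4) uses rest as a mode toggle between straight-line and
rotation, wrist flexion/extension as the mode's two motions, and fist as
stop. Motion quanta are 12 cm translations and 45° rotations at 12 cm/s
and 0.25π rad/s — one second per quantum. Design decisions where the
protocol descriptions leave room:

* **Paradigm 2 confirmation**: a command consumes its confirming pair, so
  three equal windows in a row issue one command, not two; each 125 ms
  recognition window costs its duration on the clock in addition to
  motion time (recognition is not concurrent in this paradigm). Auditory
  cue delays are not modelled.
* **Paradigms 3/4 timing**: recording is concurrent with motion, so a
  window costs clock time only when the vehicle is stopped (disagreement,
  refused toggle, or an explicit stop).
* **Paradigm 4 toggle rule**: the mode cannot change until at least one
  motion has executed in the current mode; a refused toggle is logged.
  An even number of executed switches always restores the initial mode.
* **Obstacles** are axis-aligned rectangles; a translation that would end
  inside one is refused and logged as a collision-avoidance stop (the
  original course used "simple obstacles" without collision rules).
* Headings stay on the 45° lattice by construction; poses are continuous.

`ideal_route_time()` gives the kinematic lower bound — path length over
linear speed plus total rotation over angular speed; the standard
two-loop 40 cm square course (320 cm, eight 90° turns) bounds at
320/12 + 8·2 ≈ 42.67 s. Any simulated session on that course takes at
least this long.

## Numerical choices and degenerate inputs

* Welch PSD uses a Hamming window and one-sided density scaling; MDF's
  "first bin ≥ half total" rule biases at most one bin width.
* `ar.burg` with `demean = TRUE`; constant windows error out of the
  spectral extractors rather than returning fabricated coefficients.
* The DWT zero-pads to the next multiple of `2^levels`; padding is
  energy-neutral so Parseval holds exactly.
* ICA whitening refuses linearly dependent channels (rank-deficient
  covariance) instead of regularizing silently.
* Filter linearity holds to ~1e-5 relative error — round-off amplified by
  the high-order recursive sections, not a design property.
* Confusion rows are normalized per true class, so class imbalance does
  not distort the matrix; accuracy is window-weighted.

## Problem sizes used by the test suite

The suite generates everything it needs at run time: recordings of 24–40
trials (36–60 s at 1000 Hz, four channels), feature matrices of 40–240
windows, 100-seed recovery sweeps of 80 × 20 planted matrices, and an
end-to-end pipeline on 160 windows × 168 features. These sizes were
chosen as the smallest at which the statistical properties under test
(recovery rates, chance-level permutation accuracy, CV stability) are
comfortably away from their thresholds.

## Known limitations

* The ANN backend has no early stopping and can be slow at 42·C input
  dimensions; it is the only backend whose training is not pinned to a
  handful of iterations.
* RFE retrains `O(d²)` SVMs; at d = 168 with many windows it is the
  slowest criterion (the cross-subject workflow applies it per channel at
  d = 42, which is cheap).
* MSPCA retains principal components per scale but does not additionally
  threshold wavelet coefficients; heavy in-band noise shared across
  channels is not removed.
* The WAV reader supports PCM16 and float32 RIFF files only.
* The simulator scores recognition and timing; it does not model vehicle
  dynamics (acceleration, slip) or human reaction time.
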