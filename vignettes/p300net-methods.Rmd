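---
title: "p300net: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{p300net: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the generative
model behind the synthetic oddball data, the decoding model and its
training protocol, the attribution analyses, and the places where a design
decision had to be made and why. Every empirical statement here is one the
test-suite computes; nothing is quoted from elsewhere.

## 1. The problem

In a visual oddball paradigm a rare *target* flash among frequent
*standards* (here exactly 1 target in every run of 8 flashes, hence a 1:7
class ratio) elicits a P300 — a positive, parietal-maximal ERP component
peaking roughly 300–500 ms after stimulus onset. Three questions drive the
pipeline:

1. can a compact CNN detect single-trial targets from 8-channel epochs
   under heavy class imbalance;
2. do the classifier's *input gradients* (saliency maps) localize the
   decision evidence at the right electrodes and times; and
3. can a sliding-window statistic on those gradients track a
   session-by-session *forward drift* of the P300 latency, the marker of a
   training effect?

Because no public recordings exist for the motivating paradigm, the
package answers these questions on synthetic data with known ground truth:
every recovery claim is a claim about injected structure.

## 2. The synthetic world

`sim_config()` states the paradigm: 7 sessions, 20 blocks × 10 runs × 8
trials per session and scenario, 200 ms stimulus-onset asynchrony, 100 ms
flashes, 250 Hz sampling, epochs −100…700 ms (8 × 201). Reduced presets
(fewer blocks/subjects) are used in tests purely for CPU budget; the
structure is never changed.

**Components.** An ERP component is a Gaussian bump
`a · exp(−(t − μ)² / 2w²)` projected through a rank-1 per-channel
topography with maximum 1 at its focal electrode. Real grand averages are
smooth and unimodal; a Gaussian is the simplest shape whose peak latency
and width the recovery analyses can be tested against. Defaults:

| component | peak | width (σ) | amplitude | focal electrode |
|---|---|---|---|---|
| P300 | 400 ms (session/scenario-dependent) | 45 ms | 5 µV | Pz |
| P200 | 200 ms | 25 ms | 3 µV | Cz |

**Scenario and session effects.** The "social" scenario multiplies the
P200 amplitude by 1.5 and drifts the P300 peak linearly from 400 ms
(session 1) to 340 ms (session 7); the "non-social" scenario has gain 1.0
and a flat 400 ms latency. These reproduce the qualitative structure the
analyses must detect; the magnitudes are free parameters of the simulator,
not measured values.

**Noise.** 1/f (exponent α = 1) colored noise, σ = 4 µV per channel, with
a common source mixed in at ρ = 0.3. Rationale: EEG background is
dominated by low frequencies, and σ = 4 µV against a 5 µV P300 makes
single trials genuinely ambiguous (window-mean d′ of order 1–2) while
leaving averaged ERPs clear — the regime in which P300 decoders realistically
operate in the high-80s/low-90s percent accuracy range. Chosen once, before
any acceptance measurement, and not revisited.

**Subjects.** Per subject and component, latency jitter ~ N(0, 10 ms) and
a multiplicative amplitude factor ~ N(1, 0.1), drawn from a
subject-derived seed. Non-target flashes evoke nothing by default
(`nontarget_gain = 0`): whether standards evoke a small response is
unknown for the motivating data, so the assumption is exposed as a
config knob rather than buried.

**What the generator does not emulate:** volume conduction from a head
model, eye/muscle artifacts, non-stationary noise, electrode drift or
reference changes, habituation within a session, overlapping evoked
responses from *standard* flashes. A green recovery test therefore
establishes that the pipeline measures what it claims to measure on data
with the assumed statistical structure — not that it would survive
artifact-laden clinical recordings.

## 3. Preprocessing

The chain is notch → band-pass → segment → censor → detrend/crop.

* **Filters.** No DSP library exists in the target environment, so the
  designs are implemented from the analog Butterworth prototype with
  bilinear transform: a 4th-order prototype (8th-order band-pass) at
  2–30 Hz, and a constrained biquad notch at 50 Hz with Q = 30. Both are
  applied forward–backward (`filtfilt`) with odd-reflection padding and
  steady-state initial conditions. Zero phase is essential: every latency
  quantity downstream would otherwise inherit a filter delay. The
  test-suite checks the magnitude-response posts (≥ 20 dB at 50 Hz,
  pass-band within ±1 dB, ≥ 12 dB at 0.5/45 Hz) and that an injected bump
  does not shift by more than one sample.
* **Censoring.** With a 200 ms SOA, the target's P300 (out to ~500–600 ms)
  overlaps the following trials' windows, and the preceding trial's window
  extends into the target's response. The rule implemented: for each
  target, drop the one trial immediately before and immediately after it
  *within the same run*; targets are never dropped; runs never censor
  across their boundary. A stricter reading (two trials each side) exists;
  the one-each-side reading matches the timing argument and is the
  implemented default.
* **Detrending.** Per channel and epoch, the least-squares line over the
  cropped −100…700 ms window is removed. No additional baseline
  correction is applied.

## 4. The classifier

The network is the standard compact EEG architecture for a
`channels × time` input: a temporal convolution (F1 = 8 filters, kernel
1 × 64, "same" padding, no bias) learns frequency-selective filters; a
depthwise spatial convolution (kernel 8 × 1, depth multiplier D = 2)
learns one pair of spatial patterns per temporal filter and collapses the
electrode axis; a separable convolution (depthwise 1 × 16 + pointwise)
mixes temporal features; batch norm after each convolution block, ELU
after the depthwise and separable stages, average pooling (4 then 8) and
dropout after each pooling; flatten (16 × 6 = 96) into a 2-unit dense
softmax head. For the 8 × 201 input every intermediate dimension is
asserted programmatically (`layer_shapes()`).

**Loss.** Focal loss `FL(p_t) = −(1 − p_t)^γ log(p_t)` with γ = 2;
γ = 0 reproduces cross-entropy exactly (tested to 1e−12), and the
modulating factor down-weights easy majority-class epochs, which is the
package's only counter-measure to the 1:7 imbalance (no resampling, no
class weights).

**Training.** Adam (β₁ = 0.9, β₂ = 0.999), learning rate 1.25e−4,
mini-batches of 128, up to 300 epochs with early stopping — these package
defaults mirror the protocol of clinical-scale studies, where an epoch is
hundreds of optimizer steps. Early stopping monitors validation loss
(patience 20, best weights restored) on a stratified 20 % split of the
training trials. All randomness — initialization, shuffling, the split,
dropout — derives from one integer seed, so training is bit-reproducible.

**Reduced-preset adaptation.** The acceptance experiments train on a few
hundred to ~1300 epochs, i.e. ~8–10 optimizer steps per epoch instead of
hundreds. At the default rate the optimizer would need thousands of epochs
to traverse the same distance, so the acceptance protocol scales the
learning rate to 1e−3 (roughly the step-count ratio) with 40–45 epochs.
This is a budget adaptation of the optimizer, decided from convergence
behaviour on training data only; the generator, the thresholds and the
architecture are untouched, and the package defaults remain the
clinical-scale values.

**Implementation.** No deep-learning framework is available for R in the
target environment, and the saliency module needs exact input gradients,
so forward and backward passes are hand-implemented (R orchestration, C++
kernels for the 1-D convolutions and the per-map normalization
arithmetic). Correctness is anchored by finite differences: every
parameter tensor's gradient and the input gradient are checked to relative
error < 1e−3 in the suite (they agree to ~1e−9 in practice). Batch-norm
running statistics use momentum 0.9 (faster to settle than 0.99 at small
step counts; exposed in the config). The original architecture's max-norm
constraint on depthwise weights is omitted by default — it exists for
regularization, not correctness — and dropout defaults to 0.5.

## 5. Saliency and its quantifications

For a trained network with pre-softmax class score `h_c(X)`, the saliency
map of an epoch is `M = ∂h_c/∂X` at that epoch — the weights of the local
first-order (Taylor) linearization. For an exactly linear scorer
`h_c(X) = ⟨ω, X⟩ + b` the map *is* ω for every input; `linear_oracle()`
implements that contract and anchors the module's tests. The gradient is
taken w.r.t. the pre-softmax score (the softmax saturates and shrinks
gradients without changing their pattern) for the target class on target
trials, both choices exposed as arguments.

Per-trial maps are normalized to max |·| = 1 (sign preserved — the maps
are signed) and averaged; profiles reduce |M|: per-electrode means
(spatial), per-sample means (temporal). The P300-latency proxy is the
center of the 100 ms window (5 ms grid over the whole epoch, earliest
window on ties) maximizing the mean |gradient| at Pz; window sum and max
are selectable alternatives. The session trend is the Pearson correlation
of the 7 window centers with session number, with the exact t-transform
p-value.

**Per-session models for the latency trend.** A single model trained on
session-mixed data has an essentially input-independent gradient pattern:
the temporal structure of `∂h_c/∂X` is set by the learned kernels, and the
mild ELU gating does not move the window by the ~10 ms/session the drift
produces (measured directly in development: the window center is constant
across sessions under a shared model). The drift *is* recovered when each
session is decoded by its own model — which matches the per-session
decoding framing of the motivating analyses. Two further numerical
choices stabilize the estimate: all 7 session models start from the *same*
initialization seed, so between-session differences in the maps are driven
by the data rather than by initialization noise; and the per-session map
averages the target trials of all subjects in the set. Both paths (shared
LOSO model; per-session models) are implemented and tested; the shared
model is the default for accuracy reporting, the per-session protocol for
latency trends.

## 6. Statistics

Paired t, pooled-variance two-sample t and Pearson r (with exact
t-transform p-values) are implemented from their closed forms — they are
the quantities the pipeline reports — and are cross-checked against R's
reference implementations to 1e−10 on random inputs. Degenerate inputs are
flagged, not silently passed: zero-variance paired differences error
(except the all-zero case, which returns t = 0, p = 1 by continuity),
constant series make r undefined, and a confusion matrix with an empty
class returns NaN for the affected rate with a `degenerate` flag. All
tests are two-sided at α = 0.05 with no multiple-comparison correction,
matching the reporting conventions of the field the package serves.

## 7. Known limitations

* The synthetic benchmark is a *verification* instrument, not a validation
  against clinical EEG; transfer of the accuracy numbers to real
  recordings is explicitly out of scope.
* The latency-trend protocol requires per-session retraining; with very
  few trials per session the window centers become unstable (measured in
  development), so the preset uses ≥ 3 blocks/session for that analysis.
* The LR baseline uses a 0.5 decision threshold; under 1:7 imbalance this
  yields conservative sensitivity. Threshold calibration is intentionally
  absent (the baseline mirrors the standard protocol).
* EDF input/output is not provided (binary format, no reader in the target
  environment); continuous recordings round-trip through a delimited text
  container instead.
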