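# p300net

Simulation, compact-CNN decoding and gradient-saliency analysis of P300
oddball EEG, for researchers who study single-trial event-related-potential
(ERP) decoding — e.g. attention-training studies where a rare *target*
flash among frequent *standards* elicits a parietal P300 and the question
is whether a classifier can find it, and *where and when* in the signal the
classifier looks.

The package provides, as one tested pipeline:

* **Synthetic oddball EEG.** An 8-electrode montage (C3, Cz, C4, CPz, P3,
  Pz, P4, POz) sampled at 250 Hz; epochs of −100…700 ms (8 × 201 samples);
  runs of 8 flashes with exactly one target, so the class ratio is exactly
  1:7. ERP components are Gaussian bumps in time projected through rank-1
  scalp topographies: a parietal-maximal P300 (~300–500 ms, focal Pz) and a
  weaker frontocentral P200 (~200 ms, focal Cz), on 1/f background noise.
  Scenario ("social" vs "non-social") and session effects are injectable:
  a P200 amplitude gain and a session-by-session forward drift of the P300
  latency, giving every downstream analysis a known ground truth.
* **Preprocessing.** Zero-phase 50 Hz notch and 2–30 Hz Butterworth
  band-pass (forward–backward), segmentation around event markers,
  censoring of the trials adjacent to each target (the 200 ms
  stimulus-onset asynchrony lets the P300 bleed into neighbouring epochs),
  and per-channel linear detrending with cropping to −100…700 ms.
* **A compact depthwise-separable CNN** for `channels × time` input:
  temporal convolution (8 filters, kernel 64) → batch norm → depthwise
  spatial convolution (8 × 1, depth multiplier 2) → batch norm, ELU,
  average-pool 4, dropout → separable convolution (kernel 16) → batch
  norm, ELU, average-pool 8, dropout → flatten (96) → dense softmax pair.
  Trained with Adam on the focal loss
  `FL(p_t) = −(1 − p_t)^γ · log(p_t)` (γ = 2 by default) to counter the
  1:7 imbalance. Forward, backward and *exact input gradients* are
  implemented in the package (R + a small C++ kernel); the gradients are
  verified against finite differences in the test-suite.
* **Gradient saliency analysis.** `M(i,j) = ∂h_c/∂X |_{X0}` per epoch,
  normalized to max |·| = 1 and averaged; spatial profiles (per-electrode
  mean |gradient|), temporal profiles (per-sample mean |gradient|), the
  most-varied 100 ms sliding window (5 ms steps) at Pz as a P300-latency
  proxy, and the Pearson correlation of its center with session number.
* **A logistic-regression baseline** on per-channel 350–400 ms ERP means,
  evaluated under the same leave-one-subject-out (LOSO) protocol, plus the
  paired/two-sample t and Pearson statistics used to compare conditions.

## Worked example

```r
library(p300net)

cfg <- sim_config(seed = 101, n_subjects = 4, n_sessions = 7,
                  blocks_per_session = 1, runs_per_block = 10)
ds  <- censor_adjacent(generate_dataset(cfg, scenarios = "non-social"))
ds
#> <epoch_set> 1680 epochs x 8 channels x 201 samples (-100..700 ms @ 250 Hz)
#>   targets: 280, standards: 1400

res <- evaluate_loso(ds, eegnet_config(),
                     train_config(learning_rate = 1e-3, max_epochs = 40,
                                  patience = 12, seed = 101))
res$per_subject
#>   subject accuracy sensitivity specificity   n
#> 1       1 90.92971    84.28571    92.18329 441
#> 2       2 90.41096    82.85714    91.84783 438
#> 3       3 92.87356    81.42857    95.06849 435
#> 4       4 92.16590    90.00000    92.58242 434

maps <- lapply(1:4, function(s)
  compute_saliency(res$models[[as.character(s)]],
                   epochs_subset(ds, ds$meta$subject == s & ds$labels == 1)))
grand <- average_maps(maps)
which.max(spatial_profile(grand))
#> Pz
#>  6
peak_gradient(temporal_profile(grand), c(300, 500))$latency
#> [1] 380
```

Mean held-out accuracy is ≈ 91.6 % against the 87.5 % no-information rate
of the 1:7 paradigm; the most discriminative electrode is Pz and the
temporal attribution peaks at 380 ms, within 20 ms of the mean injected
P300 latency (≈ 394 ms after per-subject jitter) — i.e. the decoder is
demonstrably reading the injected component, not a confound. The
session-latency drift analysis (per-session models, sliding-window centers,
Pearson trend) is exercised by `tests/testthat/test-acceptance.R`, which
recovers the injected social-scenario drift with mean r ≈ −0.92 across
five seeds.

A command-line front end is installed at
`system.file("cli", "p300pipe.R", package = "p300net")` with verbs
`simulate | preprocess | train | baseline | saliency | all | report`.

## Documentation

The methods vignette (`vignettes/p300net-methods.Rmd`) describes the
generative model and its defaults, the network and training protocol, the
saliency quantifications, the numerical choices, and what the synthetic
benchmark does and does not establish.
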