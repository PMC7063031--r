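# emglens

Tools for understanding what a deep network learns from surface
electromyography (sEMG), using the classical handcrafted-feature
literature as the frame of reference.

Myoelectric control — driving a prosthesis or interface from classified
EMG windows — has historically relied on handcrafted features (mean
absolute value, zero crossings, autoregressive coefficients, …).
Convolutional networks trained on raw windows now match that approach,
but what they compute internally is opaque. `emglens` provides the full
computational stack needed to compare the two feature families:

* **`signal_io`** — 10-channel, 1 kHz recordings; fourth-order
  Butterworth band-pass (20–495 Hz, designed in-package); segmentation
  into 10×151 windows (151 ms, 100 ms overlap); cycle-based
  train/validation/test splits; CSV + JSON-manifest dataset format.
* **`handcrafted`** — a 56-method / 79-output feature bank in five
  functional groups (SAP 25, FI 5, NLC 6, TSM 7, UNI 13 methods),
  computed per channel per window.
* **`convnet`** — a channel-independent ConvNet (six blocks of
  conv 1×26 → batch norm → leaky ReLU → dropout; 64 maps; 543,629
  parameters), written in R with small C++ conv kernels, with *learned
  features*: each map time-averaged per channel (6 × 64 = 384 ids).
* **`adann`** — standard aggregate training, and multi-domain
  adversarial training: per-participant batch-norm statistics, a
  2-output domain head, gradient reversal, loss `Ly + λ·Ld`.
* **`interpret`** — Guided Grad-CAM saliency maps for EMG windows and a
  Gaussian-noise probe.
* **`mapper_tda`** — the Mapper algorithm over feature point clouds
  (PCA to 99% variance → 2-D t-SNE lens, perplexity 30 → 5×5 cover at
  65% overlap → Ward partial clustering → topological graph), with
  scenarios A (handcrafted), B (learned) and C (both).
* **`downstream_eval`** — single-feature / group LDA evaluation and
  frozen-trunk regression heads from block activations to handcrafted
  features.
* **`synthetic_data`** — a multi-participant synthetic sEMG generator
  (gesture-specific channel-activation bumps; participant domain shifts:
  channel rotation, per-channel gain, noise floor) so the whole pipeline
  is testable without recordings.

## Worked example

```r
library(emglens)

# a small synthetic world: 3 participants x 3 gestures
ds <- generate_dataset(synth_config(participants = 3, gestures = 3,
                                    cycle_s = 1, cycles = 8, seed = 42))
ds
#> <emg_dataset> 1224 windows (10 x 151), 3 participants, 3 gestures

# handcrafted feature bank
reg <- feature_registry()
reg
#> <feature_registry> 56 methods, 79 scalar outputs
#>
#>  FI NLC SAP TSM UNI
#>   5   6  25   7  13

# the reference-scale network
build_model(architecture_config())
#> <emg_model> 6 blocks x 64 maps, 543,629 parameters, 0 BN bank(s)

# train a reduced network with the adversarial procedure
m <- train_adann(build_model(architecture_config(n_blocks = 2,
                                                 feature_maps = 8,
                                                 n_classes = 3), seed = 1),
                 ds, train_config(batch_size = 64, max_epochs = 3, seed = 1))
round(evaluate_cross_subject(m, ds, adaptation = "adabn"), 3)
#> 1 2 3
#> 1 1 1

# saliency for the gesture actually present in a test window
i <- split_indices(ds, "test")[1]
sal <- guided_grad_cam(m, ds$windows[, , i], ds$meta$gesture[i],
                       participant = ds$meta$participant[i])
sal
#> <saliency_map> class 0, max relevance 1.21e-07

# Mapper over the handcrafted features of a small dataset (scenario A)
tiny <- generate_dataset(synth_config(participants = 2, gestures = 3,
                                      cycle_s = 0.35, cycles = 8, seed = 11))
tabs <- list(handcrafted = compute_all(tiny, feature_registry()))
res <- run_scenario(tabs, "A", seed = 7)
unlist(res$report)
#>            scenario            n_points        n_components                  kl
#>                 "A"                "79"                "30" "0.161199554015297"
#>             n_nodes             n_edges
#>                "44"               "251"
```

The per-participant accuracies above are on each participant's held-out
test cycles after brief adversarial training of a small network — the
synthetic gestures are deliberately easy within-participant. Exact
Mapper node/edge counts depend on the dataset and t-SNE seed; the values
are what this script printed here.

## What this package does not claim

Full-scale results on real multi-participant recordings — absolute
cross-subject accuracies, the node/edge counts of topological networks
built from hundreds of thousands of windows, per-feature classification
tables — require the original data and long training runs and are out
of scope. The synthetic experiments here establish the *direction* and
*mechanics* of each analysis, never real-data magnitudes. See
`vignettes/emglens-methods.Rmd` for the full methods account and design
rationale.
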