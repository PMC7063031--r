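---
title: "Methods: interpreting learned and handcrafted EMG features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpreting learned and handcrafted EMG features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`emglens` implements a complete stack for studying what a convolutional
network learns from surface electromyography (sEMG) compared with the
classical handcrafted feature literature: preprocessing and windowing, a
56-method / 79-output handcrafted feature bank, a channel-independent
ConvNet trained either conventionally or with a multi-domain adversarial
procedure (ADANN), Guided Grad-CAM saliency, a Mapper topological-data-
analysis pipeline over feature point clouds, LDA and regression-head
probes, and a synthetic multi-participant EMG generator that makes every
stage testable without external recordings.

This vignette documents the models, the parameters that matter, the
numerical choices, and the places where the design was genuinely open.
It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

# Preprocessing

Recordings are channels x samples matrices at 1 kHz. They are band-pass
filtered with a fourth-order Butterworth between 20 and 495 Hz and cut
into 151-sample windows with a 51-sample stride (100 ms overlap) — the
window length sits inside the 150–250 ms latency budget of real-time
myoelectric control.

Two decisions were open:

* **Causality.** The filter is applied causally (forward only), matching
  online use; `zero_phase = TRUE` gives the forward–backward variant.
* **Order of operations.** We filter the whole recording and then
  segment. Filtering 151-sample windows individually leaves a visible
  edge transient in every window; a `per_window_filter` flag restores
  the strict segment-then-filter order for comparison.

The filter is designed in-package (analog prototype, low-pass to
band-pass transform, bilinear transform with prewarping); its
coefficients are pinned in the test suite against an independent DSP
implementation to ~1e-9, and the measured steady-state sine gain is
checked against the analytic frequency response.

# The handcrafted feature bank

The registry holds 56 feature methods in five functional groups — SAP
(signal amplitude and power, 25 methods), FI (frequency information, 5),
NLC (non-linear complexity, 6), TSM (time-series modelling, 7), UNI
(unique, 13) — expanding to 79 scalar outputs: AR, CC, DAR and DCC are
order-4 (4 outputs each), HIST has 3 bins, MHW and MTW 3 sub-windows
each and TSPSD 6 descriptors. This multi-output allocation is the one
consistent with standard member naming (AR2/AR4, CC1/CC4, HIST123,
MHW23, MTW123) and is configurable.

The method names are standard in the myoelectric-control literature but
the formulas are rarely given alongside them; the implementations follow
the common conventions, with these package-level choices:

* **Thresholds.** ZC and SSC use threshold 0; WAMP uses 50 amplitude
  units (the recordings are scaled to ±450-ish device units). All three
  are configurable; no canonical value exists.
* **Spectra.** One-sided rectangular-window periodogram at resolution
  `fs/N`; the 0 Hz bin is excluded from spectral peaks and moments (a
  band-passed window has no meaningful DC term).
* **Entropies.** SAMPEN and APEN use m = 2, r = 0.2·SD; a zero-variance
  window returns 0 by convention.
* **Autoregression.** Levinson–Durbin on the biased autocorrelation;
  coefficients are the predictor convention (an AR(1) process with
  coefficient 0.5 yields AR1 ≈ +0.5), and the cepstrum follows the LPC
  recursion, so CC1 equals AR1 exactly — both facts are oracle-tested.
* **Fractal / scaling estimators.** Box-counting on the min–max
  normalised curve over dyadic grids 2^1..2^5; DFA with 8 log-spaced
  window sizes in [4, N/4] and linear detrending; VFD and CE share the
  lag-1..8 increment-variance scaling exponent H (VFD = 2 − H/2, CE =
  H). The two are therefore affinely related — collinear features are
  normal in this literature (RMS and the v-order with v = 2 coincide
  too).
* **Degenerate inputs.** Every log and division is floored at 1e-12;
  all 79 outputs are finite on constant (including all-zero) windows.
  This is asserted in the tests.

# The ConvNet

Six blocks of {conv (valid padding, stride 1, kernel 1 x 26, 64 maps) →
batch norm → leaky ReLU (slope 0.1) → dropout (0.35)}, followed by two
linear heads (11 gestures; 2 domain outputs) reading the flattened
(map, channel) block-6 output. The kernel height of 1 keeps every
feature map channel-independent, mirroring how handcrafted features are
computed per channel; the time axis shrinks by 25 per block
(151 → 126 → … → 1), so block-6 maps are 10 x 1 and the head input is
64 x 10 = 640. The default model has exactly 543,629 trainable
parameters; the per-block and per-head counts are asserted against a
brute-force sum in the tests.

The engine is written in R with two small C++ kernels for the time-axis
convolution (a sum of shifted matrix products — profiling showed the
im2col route is memory-bound in this setting). The full backward pass is
verified against central finite differences at ~1e-8 relative error.

*Learned features*: after the leaky ReLU of block b, each of the 64 maps
is averaged over time per channel, giving 64 x 10 scalars per window and
6 x 64 = 384 learned feature ids. Note a bookkeeping subtlety: the
hybrid Mapper scenario is described in the source literature as 465
features, but 79 + 384 = 463; this package produces 463 and documents
the discrepancy rather than inventing two features.

*Batch normalisation banks.* The affine BN parameters are shared
weights; the running mean/variance are stored per participant (AdaBN
convention). Evaluating an unknown participant without an adaptation
policy is an explicit error. `adapt_bn()` recomputes statistics from
unlabeled windows; because train-mode normalisation uses batch
statistics, a single averaging pass over chunks is exact.

# Training

Adam at the reference initial learning rate 0.0404709, batch size 512,
learning-rate annealing by 5 with patience 15, early stop after two
consecutive annealings without a new best validation loss. Validation is
the gesture cross-entropy on cycle 4 (ADANN: averaged over participants
under their own statistics). The best-validation weights are restored at
the end (the reference procedure does not say; keeping the final weights
is the only alternative and is strictly worse under annealing).

**ADANN.** One epoch visits every participant as the *source* domain in
shuffled order and iterates over that participant's windows in batches
(the phrase "a batch is created" is ambiguous between one batch per
participant and a full pass; the full pass uses all data and is chosen
here). Each source batch (domain label 0) is paired with a target batch
(domain label 1) from one uniformly drawn other participant; the batches
pass through the network consecutively under their own BN statistics;
only source batches update stored statistics; the loss is
Ly + λ·Ld (λ = 0.1) with both heads cross-entropic; the domain-head
gradient is multiplied by −1 where it enters the shared trunk. Target
gesture labels are never used (DANN convention). With λ = 0 the domain
head provably receives no update, which is tested.

# Saliency

Guided Grad-CAM follows the four classical steps: one-hot output
gradient, guided backpropagation (negative activations and negative
backward gradients zeroed at every activation step — applied to the
final input-propagation step as well, making the map non-negative by
construction), Grad-CAM at the block-6 post-activation maps (global
average pooled class gradient as map weights, rectified weighted sum),
and point-wise fusion. Because block-6 maps have time length 1, the
Grad-CAM map is broadcast along the 151-sample axis before fusion — the
only information-preserving choice; for intermediate blocks with longer
time axes the map is linearly interpolated. Leaky-ReLU layers are
treated as the "ReLU" steps of guided backprop (negative parts zeroed in
the backward pass only). Saliency always runs in eval mode.

The noise probe feeds a zero-mean Gaussian window (SD 450, matching the
recording scale) and reports the per-class maximum saliency, to be
compared with the same quantity on real windows.

# Mapper

Each feature id becomes one point whose coordinates are its values over
all (window, channel) pairs — 79 points for scenario A (handcrafted),
384 for B (learned), 463 for C (both). Points are z-scored along their
own vector first: handcrafted features span many orders of magnitude and
Euclidean distance should reflect co-variation shape, not units (the
source literature is silent on this).

The pipeline is PCA to 99% cumulative variance, a 2-D exact t-SNE lens
(perplexity 30, deterministic given a seed, final KL divergence
reported), a 5 x 5 cell-centred cover whose regions are cells expanded
to side D = H/(1−p) at p = 0.65 overlap, Ward clustering inside each
region in the PCA space, and a graph with one node per cluster and an
edge wherever member sets intersect.

Numerical and design notes:

* t-SNE is implemented in-package: the reference configuration uses
  perplexity 30 on as few as 79 points, which common implementations
  refuse (they demand perplexity < (M−1)/3). Squared distances are
  normalised by their mean before the perplexity search, making the
  affinities — and hence the whole pipeline — exactly invariant to
  uniform translation and scaling of the cloud (tested).
* The cover uses k² cell-centred regions, matching the "grid of 25
  cubes" actually used; the (k+1)² vertex-centred textbook variant is
  available via `vertex_centered = TRUE`.
* Ward dendrograms are cut with the first-gap heuristic (merge heights
  histogrammed into ⌈√n⌉ bins over [0, max]; cut at the first empty
  bin; single cluster if none) — the classical Mapper recipe; the
  source work does not state its cut.
* Clustering operates in the post-PCA space for tractability rather
  than the raw N·C space; the graph-assembly step is verified against a
  brute-force oracle on a 20-point toy instance.

# Downstream probes

*LDA.* A compact in-package LDA (class means, pooled covariance,
empirical priors) with automatic ridge shrinkage when the covariance is
singular; it is checked against the closed-form two-class discriminant.
Protocol is cross-subject: fit on the training cycles of all
participants, test on the test cycles. A single handcrafted feature
enters as its 10 per-channel values; a single learned feature is
summarised by the first principal component of its channel values —
asymmetric, but it is what the reference evaluation literally does; a
`symmetric_pc1` flag applies PC1 to both.

*Regression probe.* A single linear output neuron reads the flattened
first-channel slice of a block's post-activation maps and is trained
(Adam, MSE) to predict a handcrafted feature's first-channel value with
all other weights frozen (bit-identity of the trunk is asserted).
Targets are z-scored on training statistics. Multi-output features are
reduced to their first principal component; the PCA is fit on the
training set and applied to the test set by default to avoid leakage
(the strictly literal per-phase decomposition is available via
`per_phase_pca = TRUE`).

# The synthetic world

The generator emulates an armband protocol: 8 participants x 5 gestures
x 8 cycles of 5 s holds, 10 channels at 1 kHz, amplitude scale 450.
Each channel carries 20–450 Hz band-limited Gaussian noise whose RMS
follows a gesture-specific circular Gaussian activation bump over the
channel axis (width 1 channel, floor 0.15), with a lognormal (SD 0.1)
cycle-to-cycle amplitude wobble. Domain shift per participant: an
integer circular channel rotation, per-channel log-uniform gains in
[0.75, 1.33], and an additive noise floor with SD in 2–8% of the
amplitude scale.

Rotation offsets default to the zero-mean symmetric assignment
(0, 1, −1, 2, −2, 1, −1, 0). This was the one genuinely delicate world
choice: a first, one-sided assignment (offsets 0–3) produced a mean
training rotation of almost two channels, and *any* channel-equivariant
method then aligns to a shifted template — cross-domain transfer becomes
unidentifiable and adversarial training lands *below* chance. Two-sided
donning variability is also the physically natural model. With it,
within-participant recognition is easy (an LDA on MAV exceeds 90%),
while naive cross-participant transfer degrades by well over 15 points —
the regime in which a domain-adversarial method has something to gain.

What a green test on this world does **not** establish: real sEMG has
motor-unit structure, nonstationarity within holds, electrode-skin
drift, and inter-gesture spectral differences that the generator does
not model. The synthetic experiments check the *direction* and
*mechanics* of the methods, never the magnitudes reported for real
recordings.

# The transfer benchmark

Demonstrating the full cross-subject advantage of adversarial training
on real recordings requires the original dataset and GPU-scale training
and is explicitly out of scope. The property substitute
(`adann_transfer_benchmark()`) keeps the direction of that effect: leave-one-participant-out on the default synthetic world, a
width-reduced network (3 blocks, 16 maps), windows thinned 20x, batch
size 64 (measured ~3x faster per window than 512 on one CPU — cache
effects), learning rate 0.005 for both methods (the reference rate
0.0404709 belongs to batch 512 and visibly diverges at batch 64), and
the genuine annealing / early-stopping schedule capped at 12 epochs;
the dataset is generated once from the base seed, with one held-out
participant rotating per training seed over three seeds, and AdaBN
adaptation for both methods at test time. These reductions scale the
experiment to a single-CPU budget; none of them touches the generator.

Folds differ sharply in difficulty by construction. With 5 gestures on
10 circular channels the activation bumps sit exactly 2 channels apart,
so an integer rotation of 2 aliases one gesture onto its neighbour
*exactly*, and a rotation of 1 lands exactly between two templates.
A held-out participant with rotation 0 (or ±2) is identifiable — the
±1-rotated training participants' data tips the interpolation toward
the canonical reading — whereas a ±1-rotated holdout is close to a
per-gesture coin flip that a channel-equivariant method tends to
resolve toward a *neighbouring* gesture, landing at or below chance.
The adversarial method consequently wins decisively where the task is
identifiable (its invariance pressure suppresses the participant-gain
memorisation that standard training falls into) and commits
all-or-nothing on the ambiguous fold. The whole pipeline — training,
AdaBN statistics collection and evaluation — is deterministic given the
seeds, so the acceptance test and the acceptance script reproduce the
same fold accuracies exactly; run `adann_transfer_benchmark()` to
obtain the numbers rather than trusting prose.

# Known limitations

* The engine is CPU-bound R + small C++ kernels; it is meant for
  reduced architectures and synthetic-scale data, not for replicating
  full-scale training runs.
* `run_scenario` clusters in PCA space; the original-space option exists
  but is slow for large window counts.
* No adapter for the original recordings' directory layout is shipped:
  the layout is not documented in the sources available here, and a
  speculative parser would be worse than none. The CSV + JSON-manifest
  format covers the same role.
* Checkpoints are plain JSON: portable and diffable, but large for
  full-width models (~10 MB) and round-trip only to ~1 ulp.
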