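---
title: "Seizure detection on encrypted EEG spectrograms: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure detection on encrypted EEG spectrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaoseeg)
```

# The problem

Continuous EEG review for seizure detection increasingly happens off the
recording device — in the cloud, on shared clinical infrastructure — which
raises a privacy question: can a classifier operate on *encrypted*
representations of the signal, so that the raw recording never leaves the
acquisition site in readable form? `chaoseeg` implements one answer: each
EEG channel is summarized as a time–frequency image, the image is scrambled
by a chaotic permutation cipher whose key stays with the data owner, and a
convolutional classifier is trained directly on the scrambled images.
Because the cipher is a *fixed* permutation of pixel positions, it is
invertible for the key holder, preserves the pixel-value histogram exactly,
and — crucially for learning — presents every image to the classifier under
the same rearrangement, so class structure survives encryption even though
visual interpretability does not.

The package is a complete, self-contained laboratory for this design:
synthetic EEG generation, Teager–Kaiser energy imaging, baker/Arnold
encryption, a compact CNN ensemble with swarm-optimized fusion weights, and
a stratified 10-fold evaluation protocol.

# The synthetic recording model

No public recording corpus ships with the package; instead
`generator_config()` / `generate_dataset()` simulate labelled segments with
the statistical features the pipeline relies on:

* **Background (all classes).** A 1/f ("pink") process built from 40
  random-phase sinusoids with frequencies uniform on 0.5–45 Hz and
  amplitudes proportional to 1/f, rescaled to a root-mean-square of
  `background_amp` (default 20 µV, a typical scalp-EEG scale), of which 80%
  of the variance is the structured 1/f part and 20% a white-noise floor.
* **Preictal.** Background plus a 7–9 Hz rhythm at 1.5 × the background
  RMS — a deliberately *mild* signature, since the preictal state has no
  agreed-upon universal marker.
* **Ictal.** Background plus a 3 Hz spike-and-wave surrogate at
  `ictal_amp_ratio` (default 5) times the background scale. The spike is a
  half-wave-rectified sinusoid sharpened by raising it to the 12th power,
  which narrows it to ≈55 ms at 3 Hz — inside the physiological 50–70 ms
  spike width — and the rectified-squared opposite half-cycle supplies the
  slow wave. The sharpening matters: the Teager–Kaiser operator weights
  energy by frequency squared, so a smooth low-frequency bump is almost
  invisible to it while a sharp transient produces a large burst. With a
  realistically narrow spike the ictal class carries an unmistakable 3 Hz
  burst comb into the energy domain.

Segments are 1, 2 or 4 s at 256 Hz, 6 channels by default (a minimal
montage of the size often retained for wearable seizure detection), and
every segment is generated from a sub-seed derived deterministically from
the dataset seed, so all downstream results are bit-reproducible.

What the generator does *not* emulate: inter-patient variability, electrode
artifacts (EMG, eye blinks, movement), non-stationary background drift, the
spatial topography of a focal onset, or a realistic preictal horizon.
Passing results on this data therefore demonstrate that the pipeline's
machinery is correct and that its stages preserve learnable structure — not
that the system would reach the same numbers on clinical recordings.

# Signal features: Teager–Kaiser energy and spectrogram images

The discrete Teager–Kaiser energy operator (TKEO)

$$\Psi(g[n]) = g[n]^2 - g[n-1]\,g[n+1]$$

estimates instantaneous signal energy from three samples; for a pure tone
$A\cos(\omega n)$ it returns the constant $A^2\sin^2\omega$, i.e. it is
sensitive to amplitude *and* frequency at once. `tkeo_discrete()`
implements exactly this, replicating the nearest interior value at the two
boundary samples where the operator is undefined. `tkeo_continuous()`
provides the continuous form $\dot g^2 - g\ddot g$ via central finite
differences.

`to_spectrogram()` turns a channel into an 8-bit image: TKEO series (the
default; the raw signal is kept as an ablation option) → Hann-window STFT →
log magnitude → per-image min–max quantization to [0, 255]. Numerical
choices:

* **Window = one second of samples** (75% overlap, FFT length the next
  power of two). A Hann window's main lobe has half-width 2/T Hz; resolving
  a 3 Hz comb demands T ≥ ~1 s. Quarter-second windows — a common speech
  default — smear the comb into the 1/f background entirely, which we
  verified empirically before fixing this default.
* **Display band 0–40 Hz** (`max_freq`). Clinical EEG content lives below
  ~40 Hz; keeping the empty upper band would devote most image rows to
  noise and dilute the informative band during the square resize.
* **Flat-image guard.** If the log-magnitude surface is constant (e.g. an
  all-zero segment) the image is all zeros rather than 0/0.
* A worth-knowing property of the TKEO default: because the operator maps
  any pure oscillation to a *constant*, the preictal 8 Hz rhythm lands in
  the image's DC row, and per-image normalization then largely erases the
  normal/preictal distinction. Ictal discharges survive as a burst comb at
  multiples of 3 Hz. The energy-domain representation is thus excellent
  for *seizure* detection and poor for preictal staging — visible in the
  package's own confusion matrices, and the reason the pipeline's default
  classification target is binary (below).

Images are resized bilinearly (`resize_image()`) to the classifier's input
side — 32 px for the compact CNN; 224/227/256 px match the published input
sizes of the optional pretrained backbones.

# Chaotic permutation ciphers

Two classical measure-preserving maps scramble the $N \times N$ image:

* **Discretized generalized baker map.** The image is cut into vertical
  rectangles of widths $n_1,\dots,n_k$ ($\sum n_i = N$); each rectangle is
  sliced into boxes of $N$ pixels and each box is laid out as a row. For
  column $r$ in the rectangle starting at $N_i$ (with $q = N/n_i$):
  $r' = q\,(r - N_i) + (s \bmod q)$, $s' = (s - s \bmod q)/q + N_i$.
  Beyond the sum constraint the implementation *requires each $n_i$ to
  divide $N$* — without that the discretized map is not a bijection, which
  the bijectivity tests enforce by enumeration.
* **Arnold cat map.** $(x, y) \mapsto (x + y,\; x + 2y) \bmod N$. On a
  finite grid its iterates form a permutation of finite period
  (`arnold_period()` finds it by brute force; e.g. period 3 at $N = 2$),
  so over-iterating silently walks back toward the identity — a practical
  reason to keep iteration counts small relative to the period.

Design choices: coordinates are 0-based $(r, s)$ with the origin at the
bottom-left (matching the "left box at the bottom" construction); when both
maps are requested the baker map is applied first, then Arnold (the
composition order is otherwise arbitrary and is fixed here once); keys
serialize to JSON with no secrecy machinery, because cryptographic strength
(diffusion, keyspace analysis) is explicitly out of scope — the cipher is a
structure-preserving pre-processing stage, not a security product.

# The compact CNN

The classifier is built from the standard layer operators, written out in
the package rather than imported from a deep-learning framework:
cross-correlation convolution (no kernel flipping), max pooling, ReLU /
sigmoid / tanh activations, one fully connected softmax stage.
Convolution runs as a vectorized im2col gather feeding base-R matrix
multiplication; gradients are hand-derived, with the input gradient
computed as a transposed-kernel correlation so the backward pass also runs
through BLAS. The unit suite pins every operator to brute-force
nested-loop oracles with exact integer arithmetic.

Training is minibatch SGD with fixed learning rate 0.02, classical momentum
0.9, and optional inverse-frequency class weighting (used by the pipeline,
where the binary target is imbalanced 2:1). Plain unaccelerated SGD was
tried first and converges too erratically on this problem at feasible epoch
counts; momentum is the smallest standard remedy and keeps runs exactly
reproducible given a seed.

The default ensemble mixes three capacities of the same two-block
architecture (5×5 then 3×3 kernels with 16/32, 12/24 and 8/16 feature
maps, 2×2 pooling, one FC layer), echoing mixed-architecture transfer
ensembles while remaining CPU-trainable in seconds. The five published
backbones (AlexNet, Darknet-19, GoogLeNet, ResNet-50, SqueezeNet) are an
optional hook (`load_pretrained_backbone()`) that activates only when
weights are available locally; nothing is downloaded.

**Classification target.** The pipeline's default is binary — ictal versus
non-ictal, with normal and preictal merged — which is the detection task
the evaluation metrics score (positive class = ictal) and avoids spending
model capacity on the normal/preictal boundary that the TKEO representation
deliberately blurs. A three-class mode is retained
(`pipeline_config(class_mode = "three")`); reported metrics are one-vs-rest
for the ictal class either way, so the two modes are directly comparable.

# Hybrid swarm optimizer (HSO)

The fusion weights of the ensemble are tuned by a hybrid swarm minimizer
combining two classic update styles. Each agent keeps a memory of its best
visited position; per iteration each agent flips a fair coin between:

* **Corvid (crow-search-style) move:** follow a random flock-mate's memory,
  $J' = J + \lambda_1\, a\, (Z - J)$ with $\lambda_1 \sim U(0,1)$ and
  flight length $a$ (constant, default 2); with probability $1 -
  P_{aw}$ the agent instead relocates uniformly in the box (the classic
  anti-stagnation escape; default $P_{aw} = 0.9$, i.e. ~10% relocations).
* **Gregarious (sparrow-style) move:** an agent worse than the global best
  contracts toward a velocity-augmented best,
  $J' = J_b' + \theta\,(J - J_b')$ with
  $J_b' = J_{best}(1 + v_1\omega) + V$; an agent already at the best is
  pushed off the worst position with an $\varepsilon = 10^{-12}$ guard
  against zero denominators. The velocity state decays as
  $V \leftarrow \omega V + v_1 U(-1,1)^d$ from $V = 0$.

Candidates are clipped to the box, and memories update only on *strict*
improvement, which makes the best-fitness trace non-increasing by
construction — a property the tests assert on every run. On the 2-D sphere
function the optimizer reliably reaches ~10⁻⁸ within 200 iterations and
beats same-budget uniform random search in essentially every seed.

`tune_fusion()` minimizes 1 − validation accuracy over weight vectors in
the unit box and *seeds the swarm with the one-hot weight vectors*, so the
tuned fusion provably never scores below the best single ensemble member on
its own validation set. Where a feature-selection mask is requested, the
trailing dimensions are thresholded at 0.5. The weights need not sum to
one; `ensemble_fuse()` renormalizes.

# Evaluation protocol

`run_pipeline()` executes, per segment length: generate → image → encrypt →
stratified 10-fold CV. Inside each fold, 20% of the training data (an
inner stratified split) is held out for fusion tuning, so the optimizer
never sees the test fold. Metrics are accuracy, sensitivity, specificity,
precision and F1 (percent, positive class = ictal; denominator-free cases
are reported as `NA`, never silently as 0), summarized as mean, median and
standard deviation across folds — both the mean-style and median-style
summaries seen in this literature are emitted, explicitly labelled.
`kruskal_wallis()` / `compare_methods()` compare per-fold metric
distributions across methods with the rank-based H test (tie-corrected,
χ² p-values, H = 0 / p = 1 by convention when every observation is tied;
0.05 threshold with no multiple-testing correction, a documented
limitation).

## Problem sizes and runtime

The reference study configuration is 200 segments per class (600 per
length), 4-second windows, 32×32 images, a three-member ensemble trained
12 epochs per fold, and 10 folds — chosen so a full run completes in
minutes on a single CPU core while keeping ≥400 training images per fold.
The miniature configurations used in the unit tests (tens of segments, 2–3
folds, few epochs) exercise the same code paths and determinism guarantees
at a fraction of the cost.

# Known limitations

* Synthetic data only; see the generator caveats above. Results quantify
  pipeline correctness and capacity, not clinical performance.
* The permutation cipher offers no diffusion; identical images encrypt to
  identical ciphertexts. Security analysis is out of scope by design.
* The TKEO default trades preictal discriminability for seizure salience;
  use `apply_tkeo = FALSE` or `class_mode = "three"` to study that
  trade-off.
* The pretrained-backbone hook defines input geometry only; transfer
  learning with real weights is intentionally left outside the package.
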