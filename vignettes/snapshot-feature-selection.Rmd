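---
title: "Snapshot-ensemble deep feature selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snapshot-ensemble deep feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

`snapshotFS` implements a four-stage pipeline for multi-class texture
classification of histology-style image tiles:

1. **Snapshot training.** One convolutional network is trained once under a
   cyclic cosine-annealing learning-rate schedule. Within each of the $C$
   cycles the rate decays along a half cosine,
   $$\alpha(t) = \frac{\alpha_0}{2}\Big(\cos\big(\tfrac{\pi\,\mathrm{mod}(t-1,\,E/C)}{E/C}\big)+1\Big),$$
   and resets to $\alpha_0$ at each cycle boundary. The reset perturbs the
   weights enough to escape the minimum reached in the previous cycle, so
   the model states saved at the $C$ cycle ends ("snapshots") are diverse
   ensemble members obtained for the price of a single training run.
2. **Feature fusion.** Each snapshot maps an image to a deep-feature
   vector tapped at the second custom fully connected layer (FC-2,
   post-activation). The per-snapshot vectors are concatenated in cycle
   order; with the reference head (FC-2 width 256) and $C=5$, the fused
   vector has $256 \times 5 = 1280$ dimensions.
3. **Feature selection.** Because all snapshots come from one network,
   the fused space carries redundancy. A sigmoid-transfer binary particle
   swarm searches mask space, scoring a candidate mask by
   $$F = \omega\,\eta + (1-\omega)\,\Delta, \qquad
     \Delta = \frac{|D|-|d|}{|D|},$$
   where $\eta$ is the accuracy of a $k$-nearest-neighbour classifier
   restricted to the selected columns and $\Delta$ rewards discarding
   features. Defaults: $\omega = 0.99$, $k = 6$, $C_1 = C_2 = 1$, 50
   iterations, 10 independent repetitions, inertia $w(t) = 1 - t/T$.
4. **Evaluation.** KNN classification on the selected columns, confusion
   matrices (rows = predicted, columns = true), per-class and macro
   precision/recall/F1, stratified $k$-fold cross-validation, and
   McNemar's continuity-corrected paired test.

A gradient-weighted class-activation mapper (`gradCAM()`) localises the
class evidence of any snapshot for qualitative inspection of snapshot
diversity.

## Backbones and the compute engine

No deep-learning framework is used: the package ships a compact, fully
deterministic CNN engine in base R (BLAS-backed `im2col` convolutions,
2x2 max-pooling, leaky-ReLU, dense layers, softmax cross-entropy, SGD
with momentum). Two trunks are provided:

* `"tiny_cnn"` — two 3x3 convolution + leaky-ReLU + max-pool stages
  (8 and 16 filters), fully trainable. This is the desk-scale workhorse:
  on 32x32 inputs its flatten width is 1024 and a 10-epoch run takes
  seconds on one CPU.
* `"mobilenet_v2"` — the full MobileNetV2 topology (stride-2 stem, 17
  inverted-residual blocks, final 1x1 convolution to 1280 channels,
  ReLU6), giving the reference flatten width of $7 \times 7 \times 1280
  = 62720$ at 224x224 input. Pretrained weights are not bundled; the
  trunk is He-initialised from the configured seed, supports the forward
  pass only, and is always frozen. Out of the box it therefore serves as
  an architecture reference and fixed projection; transfer-learned
  feature quality requires importing trained weights, which is outside
  this package's scope. The trainable path for experiments is
  `"tiny_cnn"`.

The head is always `flatten -> FC-1 -> FC-2 -> softmax` with leaky-ReLU
activations (negative slope 0.01, configurable) on the two custom layers;
reference widths are 4096 and 256. The loss is categorical cross-entropy.
Inputs in $[0,1]$ are centred to $[-1,1]$ before the trunk, matching the
channel-statistics convention of the reference trunk's pretraining
pipeline and keeping from-scratch optimisation well conditioned.

### Choices the source configuration leaves open

* **Scheduler granularity.** The schedule is applied once per epoch, not
  per batch; the learning-rate trajectory is epoch-granular.
* **Optimiser details.** Batch size (32), momentum (0.9) and the loss are
  not fixed by the reference configuration; they are surfaced in
  `trainConfig()` rather than hard-coded.
* **Cycle arithmetic.** $E$ must be an exact multiple of $C$; uneven
  cycles are rejected rather than silently floored.
* **Feature tap.** FC-2 features are taken after the activation; the
  pre-activation alternative would only rescale the negative half-axis.
* **Snapshot choice.** The checkpoint is the state after the final epoch
  of a cycle; no best-within-cycle tracking.

## Feature selection details

Positions initialise Bernoulli(0.5), velocities U[-1, 1]; velocities are
clamped to $\pm 6$ so the sigmoid transfer never saturates completely.
$r_1, r_2$ are scalar per particle per iteration by default (the velocity
update is written with scalar draws); per-dimension draws are a
`swarmConfig(per_dimension_r = TRUE)` switch. Personal and global bests
move only on strictly greater fitness, so ties keep incumbents and the
global-best trajectory is non-decreasing. The empty mask is assigned
fitness 0 — the embedded classifier is undefined on zero columns — and
can never become an incumbent. Population size is not fixed by the
reference configuration; the default is 20.

$\eta$ is measured on a validation split held out of the selection
training data, never on the final test split; the evaluation split is an
explicit argument (`runBPSO(train, eval, ...)`), so a deliberately leaky
configuration can be reproduced by passing the test split, but the
pipeline default keeps the test fold untouched until the final report.

Across the 10 repetitions the best run's mask is the reported result;
all runs are retained in `@runs` so selection rates and metric averages
can be computed. `exhaustiveSearch()` evaluates all $2^{|D|}-1$ non-empty
masks (guarded to $|D| \le 20$) and is the ground-truth optimum used to
benchmark the stochastic search; its ties break toward fewer features,
then lexicographic order.

## Evaluation conventions

With rows = predicted and columns = true, per-class precision divides the
diagonal by the row (predicted) total and recall by the column (true)
total. Published write-ups of confusion-matrix metrics sometimes swap the
two formulas relative to their declared orientation, so the orientation
is carried as an explicit field on `ConfusionMatrix` and the standard
definitions are applied under it. On class-balanced data macro averages
coincide with weighted averages, and swapping the precision/recall labels
leaves those aggregates unchanged — headline numbers are robust to the
convention.

KNN ties are resolved deterministically (a policy is required because the
default $k=6$ is even): a tied vote goes to the class of the single
nearest neighbour among the tied classes, and tied distances go to the
lower training index. Fold assignment shuffles each class with a seeded
RNG and deals round-robin, so an 8-class, 625-per-class set splits
500/125 per class under 5 folds.

`crossValidate()` operates on an assembled `FeatureMatrix` (optionally
with per-fold selection on an inner split); cross-validation with
per-fold CNN retraining is composed from `runPipeline()` stages instead,
since retraining inside the fold loop is far beyond desk scale.

## Grad-CAM

Channel weights are the spatial means of the class-logit gradient at the
last convolutional activation; the weighted activation sum is rectified,
upsampled bilinearly to the input size and then min-max normalised, so
the hottest pixel of the returned map is exactly 1 whenever any positive
evidence survives rectification (normalising before upsampling would let
interpolation pull the maximum below 1). An all-negative map degrades to
zeros with a warning. For `"tiny_cnn"` the tapped layer is the
post-activation output of the second convolution (before the final
pooling); for `"mobilenet_v2"` it is the final 1x1 convolution output.

## Synthetic data: what it emulates and what it does not

`makeTextureDataset()` produces procedural stand-ins for histology
texture tiles: per class, a sinusoidal grating (class-specific frequency
and orientation, random phase per image) plus a Poisson field of small
Gaussian blobs (class-specific density) and Gaussian pixel noise, clipped
to $[0,1]$. Frequencies default to integer cycles per image so spectral
checks land on FFT bins. The grating can be confined to a recorded
quadrant, giving localisation ground truth for activation-map tests. The
classes are designed so the two-convolution backbone separates them
within about ten CPU epochs; the desk-scale preset therefore uses
`initial_lr = 0.05` — a from-scratch CNN needs a larger step than the
`2e-4` appropriate to fine-tuning a pretrained trunk.

`makePlantedFeatures()` emulates fused snapshot features: informative
columns with separated class means (the closest pair exactly
`class_separation` apart), redundant columns that are noisy copies of
informative ones (the cross-snapshot redundancy selection should prune),
and class-independent noise columns; homoscedastic Gaussian noise
throughout. The ground-truth informative mask is recorded.

These generators validate the machinery, not the biology: passing tests
show the schedule, training loop, fusion bookkeeping, optimiser and
metrics behave as specified on data with known structure. They say
nothing about stain variability, spatial correlation of real tissue
textures, class imbalance, or the transfer value of pretrained features —
all absent from the generators by design.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data at fixed seeds: the end-to-end
preset trains the tiny backbone on 120 images (3 classes x 40, 32x32,
10 epochs in 5 cycles); the optimiser-versus-oracle benchmark uses 8
planted features (3 classes x 30 samples) where the exhaustive optimum
is computable; the recovery benchmark uses 64 columns (4 informative, 8
redundant, 52 noise; 4 classes x 60 samples) with 10 repetitions of a
20-particle, 50-iteration swarm; the architecture checks build the
full-size default backbone once and run a single 224x224 forward pass.

## Known limitations

* The pure-R engine is adequate for the desk-scale backbone but not for
  training full-size trunks; `"mobilenet_v2"` is forward-only and frozen.
* No pretrained weights ship with the package, so default
  `"mobilenet_v2"` features are a fixed random projection.
* No data augmentation, mixed precision or multi-device support.
* Competitor metaheuristics (grey-wolf, sine-cosine, gravitational,
  cuckoo, whale) are not implemented; `runBPSO()`'s
  matrix-in/`FSResult`-out contract is the interface such optimisers
  would plug into.
* t-SNE embeddings of fused features are not wrapped; any embedding
  package can consume `featureValues()` directly.
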