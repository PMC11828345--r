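---
title: "Mixed attention ensembles for esophageal motility classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed attention ensembles for esophageal motility classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-resolution esophageal manometry (HREM) measures pressure at many points
along the esophagus during a swallow and renders the result as a colour
space-time map: time runs horizontally, esophageal position vertically, and
colour encodes pressure (blue low, green moderate, red high). The upper and
lower esophageal sphincters (UES; LES/EGJ) appear as horizontal high-pressure
bands, and normal peristalsis as a smooth slanted band between them. Under
the Chicago classification, characteristic deviations from that anatomy map
to motility disorders: Achalasia type II (elevated LES pressure with
panesophageal pressurization and no peristalsis), DES (broken, high-amplitude
contraction segments), EGJOO (normal peristalsis but an obstructed, high
pressure junction), IEM (weak or absent peristalsis), and Jackhammer
esophagus (hypercontractile, repetitive high-amplitude bursts).

This package classifies such images into those five disorder categories plus
Normal with an ensemble of small convolutional networks, combining two ideas:
a channel-and-spatial attention operator (CSAE) inserted into each base
model, and a mixed voting rule for fusing the models' predictions.

```{r, eval = FALSE}
library(maensemble)
par(mfrow = c(2, 3), mar = c(1, 1, 2, 1))
for (cls in hrem_classes()) {
  img <- hrem_image(hrem_spec(cls, image_size = 128, seed = 1))
  plot(as.raster(img / 255)); title(cls, cex.main = 0.9)
}
```

## The CSAE operator

For a feature map $f \in \mathbb{R}^{C\times H\times W}$ the operator pools
two descriptors: the per-channel spatial mean $C_{avg}\in\mathbb{R}^C$ and
the per-position channel maximum $C_{max}\in\mathbb{R}^{HW}$ (positions
flattened row-major). Each passes through a learnable bias-free 1D
convolution and a softmax:

$$W_c' = \mathrm{softmax}(\mathrm{Conv1}(C_{avg})), \qquad
  W_s' = \mathrm{softmax}(\mathrm{Conv1}(C_{max})),$$

and the enhanced map is $f'[k,p] = W_c'[k]\,f[k,p] + W_s'[p]\,f[k,p]$.

Numerical choices worth stating explicitly:

* **Padding.** The 1D convolutions are length-preserving with
  *edge-replicate* padding. Replication makes the convolution
  constant-preserving, so a featureless (constant) map yields exactly
  uniform attention and the closed form $f' = v\,(1/C + 1/HW)$ for constant
  input $v$ — properties the unit tests pin down. Zero padding would break
  both at the boundary for general filters.
* **Softmax scale.** Because the attention vectors are softmax-normalised,
  their mean entry shrinks as $C$ or $HW$ grows, so CSAE scales feature
  magnitude down by roughly $1/C + 1/HW$. This follows the formulation
  literally; `rescale_attention = TRUE` multiplies $W_c'$ by $C$ and $W_s'$
  by $HW$ to restore unit mean for users who want magnitude-neutral
  attention. The default keeps the literal form.
* **Kernel size.** Default 3 for both branches (the formulation leaves it
  open); configurable per model via `csae_kernel`. Filters are initialised
  at the identity (delta) kernel plus small noise, so early training starts
  near plain softmax pooling.
* **Max-pool ties.** The channel argmax underlying $C_{max}$ takes the first
  index on ties; its subgradient routes the spatial-branch gradient to that
  channel only.
* **Gradients.** `csae_backward()` differentiates through both descriptor
  paths (mean and argmax), the softmaxes, and both filters; the test suite
  checks it against central finite differences at $10^{-6}$ tolerance.

A deliberate asymmetry inherited from the design: the channel branch reads
only $C_{avg}$ and the spatial branch only $C_{max}$. Feeding $C_{max}$ into
the channel branch as well is a conceivable variant but is not implemented.

## Base models and training

No deep-learning runtime is used: convolution (im2col), max-pooling, the
CSAE operator, backpropagation and Adam are implemented directly in R. The
bundled backbones are deliberately tiny (three or four 3×3 convolution
stages, global average pooling, a linear classifier; `tiny_cnn`,
`tiny_cnn_wide`, `tiny_cnn_deep`) so that the full ensemble trains on one
CPU core in tens of seconds at 32 px input. The original design's pretrained
backbones (ResNet18, MobileNetV3-Small, GoogLeNet, EfficientNetB0) are
recognised by `base_model_spec()` but raise an informative error: they
require a framework and published weights this package does not bundle. The
ensemble machinery is backbone-agnostic, so nothing else changes if larger
models are substituted.

Training follows the standard recipe (cross-entropy, Adam, defaults: 100
epochs, batch size 16, learning rate 0.001); each model keeps the parameters
of its best validation epoch. Each model trains independently and is then
frozen before any voting weight is computed — interleaving weight updates
with training would make the weight definitions depend on a moving target,
and freezing makes every weight reproducible from the logged accuracy
streams.

## The mixed voting mechanism

All weights live on the $n$-simplex. With per-epoch validation accuracies
$A^{(e)}_j$ logged during training:

* **Individual voting.** For each primary model $k$, start from a
  primary-heavy prior (0.55 on $k$, $0.45/(n-1)$ elsewhere) and apply the
  multiplicative update $w_j \leftarrow w_j A_j / \sum_m w_m A_m$ once per
  epoch; the trajectory point (prior included) with the best ensemble
  validation accuracy is $W_k$. The $n$ sets are blended with
  $\alpha_i = e^{A_i}/\sum_j e^{A_j}$ (final validation accuracies) into
  $W_i = \sum_k \alpha_k W_k$.
* **Group voting.** `restarts` (default 32) flat-Dirichlet simplex draws are
  each evolved by the same update through the epoch stream; all trajectory
  points are candidates and the one maximising validation accuracy (ties to
  the lowest index) is $W_g$.
* **Mixed.** $W = \beta_1 W_g + (1-\beta_1) W_i$, default $\beta_1 = 0.2$.

Decisions taken where the formulation was open or inconsistent:

* **Accuracy scale in the exponential coefficients.** Accuracies enter as
  fractions in $[0,1]$. On the percent scale the exponentials become nearly
  winner-take-all (and can overflow); on the fraction scale the coefficients
  are gently monotone, which matches the reported behaviour of near-equal
  $\alpha$ for near-equal models. A `temperature` parameter sharpens the
  weighting for users who want the other regime.
* **Renormalisation.** The multiplicative update is renormalised onto the
  simplex. The uniform rescale changes no argmax downstream but keeps every
  stored vector a valid convex-combination operand.
* **Validation, not test.** All weight updates and selections use validation
  accuracy only; the test split is touched once, for the final report.
  (Accounts of such procedures sometimes mention test accuracy for the
  update step; using it would leak the evaluation set into the fit.)
* **The β₁ contradiction.** The source material for this design states in
  one place that β₁:β₂ = 4:1 is best and selects β₁ = 0.2 (i.e. 1:4) in its
  ablation table. The default follows the ablation table's selected value;
  `beta_sweep()` lets users examine the whole range on frozen predictions.
* **Fusion on probabilities.** Models are fused on softmax probabilities,
  not logits, so the fused vector is itself a distribution and one-hot
  weights reduce exactly to a single model.

`voting_mode` exposes the ablation grid: `average` (uniform $1/n$),
`standard` (weights proportional to validation accuracy), `individual`,
`group`, and `mixed`.

## The synthetic data generator

`hrem_dataset()` draws stylised HREM topographies: a latent pressure field
in $[0,1]$ with a UES band (rows 4–12% of height), an LES/EGJ band (86–94%),
and class-specific structure between them — a Gaussian-profile diagonal wave
for peristalsis, on/off gating for broken contractions (DES), parallel
repeated bursts (Jackhammer), a full-height uniform pressure column
(Achalasia II), faint waves (IEM) and an elevated LES band (Achalasia II,
EGJOO). One editable table (`hrem_class_params()`) holds all per-class
amplitudes. Gaussian noise with `noise_level` standard deviation (default
0.05 of the dynamic range) is added on the latent scale before colourisation
through a fixed blue→green→red piecewise-linear map whose stops were chosen
so grayscale luminance increases monotonically with pressure.

These are caricatures: classes are cleanly separable by construction (a
multinomial-logistic probe on 16×16 grayscale downsamples exceeds 50%
5-fold-CV accuracy on every tested seed, versus 16.7% chance). Passing the
end-to-end tests therefore demonstrates that the pipeline — generator,
split, training, attention, voting, evaluation — is wired correctly and
learns a learnable signal; it says nothing about accuracy on clinical HREM
data, which exhibit anatomical variability, artefacts and class overlap the
generator does not model. The generator also ignores manometric physiology
(no pressure time series, no Achalasia types I/III).

## Data pipeline conventions

* **Split rule.** Per class of size $n$: validation and test each get
  $\lfloor 0.2n \rfloor$ images, training the remainder — the only rounding
  of a 6:2:2 ratio consistent with the published per-class table this
  package reconstructs in its tests.
* **Eight-fold augmentation.** "Expanding the training set to eight times"
  is read as original + 7 augmented copies (`copies_per_image = 7`), which
  reproduces the published augmented counts exactly and keeps the clean
  originals in the training set.
* **One transform per copy.** Each augmented copy applies exactly one
  transform drawn uniformly from {brightness 1.6–2.0×, contrast+saturation
  2.1–2.5×, rotation ±10°, scaling 0.5–0.9, Gaussian noise, salt-and-pepper
  noise}; a `compose` flag applies all six in sequence instead. Noise
  magnitudes (σ = 0.02 of range; 1% of pixels) are package defaults, since
  the augmentation recipe this follows does not state them.
* **Border replication.** Rotation and scaling resample bilinearly about the
  centre with edge clamping rather than zero fill: black corners would be a
  trivially class-correlated artefact on synthetic data.

## Problem sizes and determinism

The shipped tests train two-model ensembles on 32 px synthetic images — 12
per class (3 epochs) for contract tests and 60 per class (10 epochs) for the
end-to-end property that test accuracy exceeds 0.8; the acceptance script
repeats the latter. These sizes were chosen so the whole suite runs in a few
minutes on a single core while still exercising every code path, including
CSAE backpropagation and all five voting modes.

Every random stream (image noise, splits, augmentation draws, weight
initialisation, simplex restarts, epoch shuffles) takes a named sub-seed
derived from one master seed, so identical configurations reproduce
identical reports byte for byte; `run_from_config()` embeds the config echo
and a deterministic run id in its JSON report.

## Known limitations

* The tiny backbones underfit anything harder than the synthetic classes;
  clinical use would require real backbones and data this package does not
  ship.
* Softmax attention's magnitude shrinkage (above) means CSAE interacts with
  classifier weight scale; `rescale_attention` exists but changes the
  operator away from its literal definition.
* One weight per model: no per-class weight vectors, no learned gating.
* Published per-class metric tables for this family of models mix
  aggregation conventions; this package's reports always label micro, macro
  and weighted aggregates explicitly rather than imitating any one table's
  convention, and its tests assert only the internally consistent published
  values.
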