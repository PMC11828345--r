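# maensemble

Classification of esophageal motility disorders from high-resolution
esophageal manometry (HREM) images with a **mixed attention ensemble**.

HREM renders swallowing pressure along the esophagus as a colour space-time
topography (red = high pressure, blue = low). Clinicians read these plots —
sphincter bands, peristaltic waves, pressurization patterns — to diagnose
motility disorders under the Chicago classification. This package implements
an automated six-class classifier for that task (Achalasia type II, DES,
EGJOO, IEM, Jackhammer esophagus, Normal), aimed at people studying
ensemble methods for medical image classification. It ships a synthetic
HREM-style image generator, so the entire pipeline runs and is tested
without any clinical data.

## The method

Each of n small convolutional base models produces a feature map
f ∈ R^(C×H×W) which is enhanced by a **channel-and-spatial attention**
operator (CSAE) before the classifier:

- pooled descriptors: C_avg ∈ R^C (spatial mean per channel) and
  C_max ∈ R^(H·W) (max over channels per position);
- attention vectors: W_c′ = softmax(Conv1(C_avg)),
  W_s′ = softmax(Conv1(C_max)), each a learnable bias-free 1D convolution
  followed by softmax;
- enhancement: f′[k, p] = W_c′[k]·f[k, p] + W_s′[p]·f[k, p].

The base models' class probabilities are fused with a weight vector W on the
n-simplex obtained by **mixed voting**:

- *individual voting*: one pass per model as "primary", evolving a
  primary-heavy prior (0.55 / rest) by the multiplicative update
  w_j ← w_j·A_j / Σ_m w_m·A_m over per-epoch validation accuracies, giving
  W_1…W_n; these are blended with exponential-accuracy coefficients
  α_i = e^{A_i} / Σ_j e^{A_j} into W_i = Σ α_k W_k;
- *group voting*: random simplex points evolved by the same multiplicative
  update; the trajectory point with the best validation accuracy is W_g;
- *mixed*: W = β₁·W_g + (1 − β₁)·W_i, with β₁ = 0.2 by default.

Evaluation reports the confusion matrix and accuracy, error rate, precision,
recall and F1 — per class and with micro, macro and support-weighted
aggregation.

## Worked example

Generate a synthetic dataset, split it 6:2:2, train a two-model CSAE
ensemble and inspect the mixed-voting weights (about a minute on one CPU
core):

```r
library(maensemble)

dir <- tempfile("hrem_demo_")
manifest <- hrem_dataset(n_per_class = 60, seed = 1, dir = dir, image_size = 32)
manifest <- stratified_split(manifest, seed = 2)

specs <- list(
  base_model_spec("tiny", "tiny_cnn"),
  base_model_spec("tiny_wide", "tiny_cnn_wide")
)
fit <- mae(manifest, specs, mae_config(seed = 3, epochs = 10, image_size = 32))
print(fit)
```

```
Mixed attention ensemble
  base models: tiny, tiny_wide
  voting mode: mixed (beta1 = 0.2)
  final weights W: (0.5075, 0.4925)
  test accuracy: 1.0000 on 72 samples
```

`summary(fit)` breaks the weights into their parts — per-model validation
accuracy A_i, the α coefficients, W_i, W_g and the blend W:

```
     model      backbone csae val_accuracy alpha W_individual W_group      W
      tiny      tiny_cnn TRUE            1   0.5          0.5  0.5373 0.5075
 tiny_wide tiny_cnn_wide TRUE            1   0.5          0.5  0.4627 0.4925
```

Both models end at validation accuracy 1 on this easy synthetic set, so the
individual weights are exactly uniform and the final W differs from 0.5 only
through the searched group component. `beta_sweep(fit, c(0, 0.2, 1))`
re-evaluates the frozen ensemble across β₁ without retraining; β₁ = 0
reproduces pure individual voting and β₁ = 1 pure group voting:

```
 beta1 accuracy precision_macro recall_macro f1_macro        w1        w2
   0.0        1               1            1        1 0.5000000 0.5000000
   0.2        1               1            1        1 0.5074575 0.4925425
   1.0        1               1            1        1 0.5372877 0.4627123
```

`predict(fit, image)` classifies new images; `coef(fit)` returns W;
`plot(fit)` shows the per-epoch validation-accuracy streams that drive the
weight updates. A thin command-line wrapper lives in `inst/cli/mae.R`
(`synth`, `prepare`, `train`, `sweep-beta` subcommands over YAML configs;
see `?run_from_config`).

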