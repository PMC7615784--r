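---
title: "Methods: GAN-augmented blood-cell classification with randomized-network ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GAN-augmented blood-cell classification with randomized-network ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlbcnet)
```

## The problem and the model

Differential white-blood-cell counts — how many neutrophils, eosinophils,
monocytes, and lymphocytes appear in a stained smear — are a routine but
labor-intensive diagnostic readout. `dlbcnet` implements a four-stage
automated classifier for such images:

1. **Augmentation (BCGAN).** Labeled medical image sets are small; a
   generative adversarial network is trained *per class* on the training
   split and used to synthesize additional images. The two players optimize
   the empirical minimax value
   $$F(D, G) = \tfrac1n\sum_i \log D(x_i) + \tfrac1n\sum_i \log\{1 - D(G(z_i))\},$$
   the discriminator ascending it and the generator descending its second
   term. The variant implemented here uses five upsampling convolution
   blocks in the generator, kernel size 5 (larger kernels temper the
   checkerboard artifacts of small-kernel upsampling), and batch
   normalization plus dropout in both players. Synthetic images are added
   to the *training* split only; test sets always contain original images
   exclusively.

2. **Feature learning.** A convolutional trunk ending at a global pooling
   layer is kept frozen; a six-layer head — `FC128, ReLU, BN, FC4,
   Softmax, Classification` — is appended and fine-tuned with
   cross-entropy. The FC128/ReLU/BN "buffer" layers smooth the reduction
   from the trunk's pooled width (2048 for the customary large backbone)
   to the 4-way classifier. Features for the next stage are tapped at the
   FC128 output, *pre*-ReLU: the layer that remains once the last five
   head layers are removed.

3. **Randomized-network classification.** Three single-hidden-layer
   networks share the same construction: hidden weights $w_j$ and biases
   $b_j$ drawn once, i.i.d. uniform on $[-1, 1]$, and never updated;
   hidden activations $H_{ij} = g(w_j \cdot x_i + b_j)$ with sigmoid
   $g$; and output weights solved in closed form against the one-hot
   label matrix $Y$ by the Moore–Penrose pseudo-inverse:
   * ELM: $P = H^{+} Y$;
   * RVFL: $P = M^{+} Y$ with $M = [X \mid H]$ (direct input–output
     links);
   * SNN: $[P; e] = [H \mid \mathbf 1]^{+} Y$ (a trainable output bias).

   No back-propagation, no iterations: one SVD per fit, and the returned
   solution is the minimum-norm minimizer of the Frobenius residual.

4. **Ensembling (ETRN).** The three member predictions are combined by
   majority vote: if any two members agree the agreed label wins;
   otherwise the ELM's label is returned. The fallback choice is treated
   as normative — the rule is exactly label voting with an ELM tiebreak,
   not probability averaging.

Evaluation is one-vs-rest: per class, counts TP/FP/TN/FN with
$TP+FP+TN+FN = N$, the five metrics (accuracy, sensitivity, precision,
specificity, F1) per class, and *unweighted* macro averages across
classes, deliberately unweighted even under class imbalance. Repeated
runs (re-randomized hidden layers on fixed features) are summarized by
the element-wise mean of per-class metrics, with macro averages
recomputed from the aggregated values; rounding to the 2-decimal
percentage scale happens only at printing time.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `Z` | 400 | hidden nodes per randomized network |
| `activation` | sigmoid | hidden nonlinearity $g$; tanh/relu available |
| `lambda` | 0 | optional ridge term; 0 = pure pseudo-inverse |
| `mini_batch` | 10 | fine-tuning batch size |
| `max_epoch` | 1 | fine-tuning epochs (guards against overfitting) |
| `learning_rate` | 1e-4 | Adam step size (fine-tuning and GAN) |
| `noise_dim` | 100 | GAN latent dimension |
| `gen_blocks` | 5 | generator upsampling blocks (each doubles resolution) |
| `kernel_size` | 5 | GAN convolution kernels (validated ≥ 4) |
| `dropout_rate` | 0.3 | dropout in both GAN players |
| `n_synthetic_per_class` | 3000 | synthetic images per class at full scale |

## Design choices where the design was open

* **Freeze policy.** The head is the only trainable part; the entire
  pre-trained trunk is frozen. Fine-tuning therefore computes trunk
  features once and optimizes the head on them, which makes the freeze
  contract exact (bit-identical trunk weights) and the epoch loop cheap.
* **Feature tap point.** Pre-ReLU FC128 output, because exactly five
  layers (ReLU, BN, FC4, Softmax, Classification) are replaced by the
  randomized networks.
* **Optimizer and loss.** Adam with categorical cross-entropy on the
  softmax output; the reference setting fixes the learning rate but not
  the optimizer, and Adam is the convention of the surrounding
  literature.
* **RVFL design matrix.** The output weights are solved on the
  concatenation $[X \mid H]$ (the standard RVFL, and the reading
  consistent with the definition of $M$); `use_direct_links = FALSE`
  gives the alternative solve on $H$ alone.
* **SNN bias.** The weight/bias pair is solved jointly on $[H \mid
  \mathbf 1]$, the natural reading of a pseudo-inverse fit "with output
  bias"; the extra free column can never worsen the optimum, which the
  tests assert as a nested-model property.
* **Random initialization.** Uniform $[-1, 1]$ for hidden weights and
  biases, seeded; the distribution is a convention of the randomized-
  network literature rather than a tuned choice.
* **Per-class GANs.** One BCGAN per class rather than a label-conditioned
  generator — the simpler reading of per-class synthesis, and it keeps
  class identity exact by construction.
* **Generator geometry.** "Five filters added" is realized as five
  upsampling convolution blocks whose widths double toward the coarse
  end from `base_filters`; the GAN renders at 64×64 by default and
  output images are bilinearly resized to the classifier input.
* **Voting fallback.** Three-way disagreement returns the ELM label; the
  rule is symmetric in the RVFL/SNN slots and asymmetric only in that
  branch.

## Numerical choices

* **Pseudo-inverse.** SVD with singular values below
  `eps * max(dim)` (relative to the largest) treated as zero — the
  minimum-norm least-squares solution even for rank-deficient or
  underdetermined ($Z > N$) systems. An all-zero design yields zero
  weights with a warning.
* **Prediction ties.** Argmax over raw outputs with ties broken toward
  the lowest class index (softmax would not change the argmax).
* **Zero denominators.** Per-class metrics with empty denominators are
  NaN with a warning, never silently 0, and NaN propagates loudly into
  macro means: silent substitution would fabricate scores.
* **ROC/AUC.** Trapezoidal integration over unique score thresholds;
  tied scores advance both rates simultaneously, so the area equals the
  pairwise concordance probability with ties counted ½ (asserted against
  a concordance oracle to 1e-10).
* **GAN scores.** Discriminator outputs are clamped to
  $[10^{-7}, 1 - 10^{-7}]$ inside logs; a non-finite loss aborts with
  the iteration index.
* **BN.** Batch statistics during training with momentum-0.9 running
  estimates for inference; inference is therefore a pure function of
  weights and input.

## What the fixtures emulate — and what they do not

`make_synthetic_cell_images()` renders class $k$ as a pale textured
background with $k$ elliptical "nucleus" blobs in a class-specific hue
with jittered geometry, so classes are separable by simple color
statistics (a mean-color nearest-centroid oracle exceeds 0.90 held-out
accuracy). `make_gaussian_features()` draws isotropic unit-variance
clouds at distance `separation` along fixed orthogonal directions;
separation 0 is chance-level, separation 10 essentially linearly
separable. These fixtures exercise every pipeline contract — counts,
determinism, freeze, voting, metric arithmetic — at desk scale, but they
share none of the hard characteristics of real stained smears (staining
variability, touching cells, class-dependent morphology rather than
color, label noise). Passing tests therefore demonstrate algorithmic
correctness, not clinical performance; the published full-scale results
additionally require the external image corpus and a large pre-trained
trunk, both outside this package's scope.

Problem sizes in the shipped tests and acceptance script were chosen at
desk scale: feature-cloud runs use 100 samples per class at dimension
32 with `Z = 400`; GAN smoke runs use 16×16 images, batch 8, 50
iterations; the reference aggregation arithmetic runs on the shipped
five-run table. The fine-tuning example below is likewise small.

## A worked desk-scale run

```{r pipeline, eval = FALSE}
cfg <- dlbcnet_config(mode = "features", n_per_class = 100, Z = 400,
                      feature_dim = 32, separation = 10, seed = 1)
run <- run_dlbcnet(cfg)
format_metrics_percent(run$report)
run$auc
```

On these separable clouds the ensemble reaches 100% macro accuracy and
per-class AUC 1.0 — the expected outcome for the null geometry, useful
as an end-to-end contract rather than as evidence about images.

The cross-run aggregation arithmetic can be checked directly against the
shipped reference tables:

```{r reference}
macro_average(reference_class_averages())
format_metrics_percent(aggregate_runs(reference_runs()))
```

## Known limitations

* The convolutional substrate is a compact pure-R implementation tuned
  for clarity and small inputs; it is not a GPU framework, and full-scale
  (224×224, tens of thousands of images) training is out of its intended
  range.
* No pre-trained ImageNet trunk ships with the package; `random_trunk()`
  provides the frozen-trunk contract at any width, and any object
  exposing a pooled-vector endpoint can be substituted.
* The GAN has no quality scoring (FID/IS) and no conditional-label
  embedding; augmentation quality is judged only through downstream
  classification.
* One reference-table cell (eosinophil specificity) is internally
  inconsistent with its own per-run rows; see `?reference_class_averages`.
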