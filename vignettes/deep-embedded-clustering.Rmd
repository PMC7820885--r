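---
title: "Deep embedded clustering: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep embedded clustering: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepclust)
```

## The model

`deepclust` implements the two-phase deep-clustering recipe that underlies
the DEC family of methods. Phase 1 learns a nonlinear map
$f_\theta : \mathbb{R}^D \to \mathbb{R}^d$ (the encoder of an autoencoder)
by minimizing a reconstruction objective, so that the latent features
$z_i = f_\theta(x_i)$ retain the information needed to rebuild $x_i$.
Phase 2 clusters in the latent space and *hardens* the clustering: given
centroids $\mu_j$, the soft assignment of sample $i$ to cluster $j$ is a
Student's-$t$ kernel on latent distance,

$$q_{ij} = \frac{(1 + \|z_i - \mu_j\|^2/\alpha)^{-\frac{\alpha+1}{2}}}
                {\sum_{j'} (1 + \|z_i - \mu_{j'}\|^2/\alpha)^{-\frac{\alpha+1}{2}}},$$

and the auxiliary target distribution squares and frequency-normalizes it,

$$p_{ij} = \frac{q_{ij}^2 / f_j}{\sum_{j'} q_{ij'}^2 / f_{j'}},
  \qquad f_j = \sum_i q_{ij}.$$

Minimizing $KL(P \| Q)$ with $P$ held fixed pulls confident points toward
their centroids and pushes centroids toward their confident points; the
closed-form gradients

$$\frac{\partial L}{\partial z_i} = \frac{\alpha+1}{\alpha} \sum_j
  \Big(1 + \tfrac{\|z_i-\mu_j\|^2}{\alpha}\Big)^{-1} (p_{ij} - q_{ij})(z_i - \mu_j),
  \qquad
  \frac{\partial L}{\partial \mu_j} = -\frac{\alpha+1}{\alpha} \sum_i (\cdots)$$

are backpropagated through the encoder while the centroids are updated as
free parameters. The total objective is the convex combination
$L = \sigma\, L_{KLD} + (1-\sigma)\, L_{AE}$.

Assumptions worth stating plainly: the method presumes that (i) cluster
structure exists in some smooth nonlinear projection of the data, (ii) the
number of clusters $K$ is supplied (the Elbow/WCSS and NMI sweeps help
choose it), and (iii) clusters are roughly unimodal in the latent space —
the Student's-t kernel is unimodal per centroid. Density-based structure
(arbitrary shapes, noise points) is served by the pipeline mode instead,
which runs DBSCAN/OPTICS directly on the latent features; those algorithms
have no centroid update rule, so they deliberately do not participate in
joint training.

## Backbone families

* **dense / stacked_denoising** — multilayer perceptron encoder with a
  mirrored decoder. Hidden activations are ReLU; the latent layer and the
  reconstruction layer are linear. The stacked-denoising variant is
  initialized by greedy layer-wise pretraining: each encoder/decoder pair
  is trained as a two-layer denoising autoencoder (dropout masking of both
  the input and the hidden code; ReLU everywhere except the first pair's
  decoder and the last pair's encoder, which are linear), pairs are then
  concatenated — encoders in training order, decoders reversed — and the
  deep autoencoder is fine-tuned end-to-end on clean inputs.
* **variational** — dense trunk with mean and log-variance heads; trained
  on the negative ELBO (squared-error reconstruction of one reparameterized
  sample plus the closed-form Gaussian KL to the standard-normal prior).
  `encode()` returns the posterior mean: downstream clustering needs a
  deterministic representation, so sampling happens only inside training.
* **convolutional** — stride-1 same-padding convolutions with ReLU and
  non-overlapping max-pooling per stage, a linear dense map to the code,
  and a mirrored decoder of nearest-neighbour upsampling + convolution with
  a sigmoid output keeping intensities in $[0,1]$. Presets reproduce the
  published 4-stage channel schedule at a configurable scale.
* **recurrent** — single-layer LSTM encoder-decoder. The encoder's final
  hidden state is the fixed-width representation and seeds the decoder,
  which is teacher-forced to reproduce the sequence *in reverse order*; the
  loss is the per-sequence sum of squared errors. Joint (gradient-through-
  encoder) clustering is not wired for this family; latent features feed
  the pipeline mode.

One printed layer schedule gives the input width of the variational preset
as "32 × 1048,576" while its dataset has 20,531 attributes; the preset
therefore parameterizes the input width instead of hard-coding either
number.

The denoising objective in the source formulation is written
$|\tilde{x} - g(f(x))|$, which is ambiguous about which copy is encoded.
The package follows standard denoising-autoencoder practice: the
*corrupted* input is encoded and the loss is squared error against the
*clean* target; at corruption rate 0 this reduces exactly to the plain
reconstruction loss. Dropout corruption masks without rescaling the
surviving units — it is corruption noise, not inverted dropout.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 1 | Student's-t degrees of freedom; fixed (cross-validating it is not possible unsupervised, and learning it adds nothing) but exposed. |
| `sigma` | 1 | Clustering-loss weight in phase 2. 1 = hard schedule (reconstruction pretraining, then pure hardening); constant values in (0,1) give joint training. Both modes are provided because the source describes both; neither is claimed to be the one behind the published tables. |
| `tol` | 0.1 (%) | Stop when fewer than this percentage of samples change hard assignment between consecutive target refreshes. The source writes "tol%" without a value; 0.1% follows the convention of the cited deep-embedded-clustering work. |
| `update_interval` | 140 steps | Optimizer steps between target-distribution refreshes. |
| `batch_size`, `lr` | 32, 1e-3 | Adam minibatch settings (the source names Adam/AdaGrad/RMSprop without values; Adam at its canonical rate is the field default). |
| `corruption_rate` | 0.2 | Dropout masking probability, matching the published "dropout rate of 20%" schedules. |
| `mean_min`, `sd_min` | 0.4, 0.75 | Post-log gene-filter thresholds; a gene is removed when mean < 0.4 OR SD < 0.75. |
| `validation_fraction` | 0.1 | Held-out share for $G = L_{train}/L_{validation}$, with the split seed recorded in the fit. |

Loss reductions are documented rather than left implicit: reconstruction
losses are the *mean over samples* of per-sample *sums over features*
(sequences additionally sum over timesteps); the KLD loss is reported per
sample. KL divergences use natural logarithms (NMI is base-invariant; the
value of the KLD loss is not, so the base is pinned).

## Interpretation choices on under-specified points

* The gene filter applies *after* the log transform (the source does not
  say; post-log is the scale on which its thresholds are plausible) and the
  SD uses the $n-1$ sample denominator.
* The combined-loss equation in the source overloads two symbols; the
  plainly intended convex combination is implemented.
* Agglomerative initialization uses Ward linkage on Euclidean distances;
  GMM initialization uses mclust's full-covariance fit; OPTICS extracts
  clusters by cutting the reachability profile at `eps_cl` (equivalent to
  DBSCAN at that radius up to border points) — a simpler, well-defined
  extraction chosen over steep-area heuristics.
* Metrics treat density-based noise labels (−1) as singleton clusters by
  default, with `noise = "drop"` to exclude them; the published tables
  report metrics for DBSCAN/OPTICS without stating a policy.
* Homogeneity and completeness follow the V-measure conditional-entropy
  definitions (`1 - H(y|c)/H(y)` and `1 - H(c|y)/H(c)`), with the value
  defined as 1 when the reference entropy is zero.
* If a cluster's hard-assignment count reaches zero at a refresh, its
  centroid is re-seeded at the least-confidently assigned sample, keeping
  $K$ fixed.
* In `sweep_k()`, WCSS is computed in the *shared pretrained* latent space
  (cluster centres = per-label means there) rather than in each run's final
  latent space: hardening rescales every run's latent geometry differently,
  so per-run WCSS values are not comparable across $K$ and the Elbow curve
  would be meaningless. The Elbow knee is the maximum discrete second
  difference, ties broken toward smaller $K$.

## What the synthetic generators emulate — and what they do not

Each generator plants class structure in *disjoint feature blocks* so the
ground truth is unambiguous and recovery tests are deterministic up to
sampling noise:

* `make_blob_dataset()` draws Gaussian components in a small latent space
  (minimum centroid spacing = `separation × noise_sd`) and embeds them in
  the ambient space through a random *orthonormal* linear map followed by
  the elementwise nonlinearity $g(x) = x + \tanh(x)$. $g$ is bi-Lipschitz
  with slope in $(1, 2)$, so pairwise separations survive within a factor
  of two: the embedding is genuinely nonlinear, yet the planted structure
  remains recoverable — the property every downstream test relies on. A
  saturating nonlinearity would silently destroy it.
* `make_expression_dataset()` produces non-negative FPKM-like values with
  per-subtype signature-gene blocks (+4 log2 units in their own subtype)
  and exactly `n_low_info` genes built to fail the low-information filter
  (half near-silent: post-log mean < 0.4; half near-constant: post-log
  SD < 0.75). A deterministic fix-up pass guarantees informative genes pass
  the filter under any seed.
* `make_image_dataset()` renders small textured RGB images (stripes,
  checkerboards, blobs, gradients) on class-specific base intensities.
* `make_text_dataset()` draws 80% of each document's tokens from a
  class-private vocabulary block, with ratings sampled so the
  rating-to-polarity thresholds reproduce the labels exactly.

They deliberately do **not** simulate realistic RNA-seq count noise
(negative-binomial dispersion, library-size effects), histology appearance,
or natural language. Passing the recovery tests therefore demonstrates that
the machinery — representation learning, hardening, metrics — behaves
correctly when the assumed structure is present; it does not certify
performance on real data, where the structure assumption itself is the
scientific question.

## Numerical choices

* Soft assignments are normalized in log space (`log1p` of scaled squared
  distances, row-max subtraction before exponentiation) so distant points
  cannot underflow all kernels to zero.
* The target distribution is computed as $q \cdot (q/f)$ rather than
  $q^2/f$: algebraically identical, and exact in the single-sample case
  where $f = q$ and $P$ must reduce to $Q$.
* All backpropagation is hand-written and validated against central finite
  differences; gradient tests use smooth activations or nudge parameters
  off exact zeros, because zero-initialized biases can leave ReLU units
  exactly at the kink where the two subgradients differ legitimately.
* $0 \log 0 = 0$ in all entropies and KL divergences; a zero assignment
  probability under positive target mass raises a classed error rather
  than returning `Inf` silently.
* Every stochastic routine takes a `seed` and runs under a
  save-and-restore RNG guard, so identical `(params, seed)` reproduce
  results bit-identically and library calls never disturb the caller's RNG
  stream.

## Problem sizes in the test suite

The suite exercises the full pipeline at desk scale: 600-sample, 50-feature
blob fixtures for recovery, pretraining-benefit and Elbow experiments;
8×8 to 16×16 images for the convolutional family; sequences of length ≤ 15
for the recurrent family; exhaustive metric oracles over all partitions of
up to 6 items into ≤ 3 blocks plus hundreds of random instances. These
sizes were chosen so every experiment is a deterministic, seconds-scale
computation a reviewer can rerun; the implementations themselves have no
size-specific assumptions beyond memory.

## Known limitations

* Pure-R training: suitable for the thousands-of-samples,
  hundreds-of-features regime; no GPU path, no batch normalization (preset
  specs record the flag, the desk-scale trainer omits it).
* Joint (gradient-through-encoder) clustering covers the dense,
  stacked-denoising, variational and convolutional families; the recurrent
  family clusters in pipeline mode only.
* No adversarial backbones, no pretrained feature extractors, no word
  vectors trained on external corpora (a word2vec text-format hook accepts
  user-supplied vectors).
* The generalizability ratio $G$ compares reconstruction losses on a 90/10
  split; it diagnoses representation overfitting, not clustering validity.
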