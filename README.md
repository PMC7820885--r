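# deepclust

Deep embedded clustering for biological data in R.

High-dimensional biological measurements — bulk and single-cell expression
matrices, microscopy images, text with ordinal ratings — rarely cluster well
in their raw representation. `deepclust` is for analysts who want to cluster
such data the way the deep-clustering literature does: learn a
low-dimensional latent representation with an autoencoder, cluster in that
latent space, and then *harden* the cluster assignments by backpropagating a
clustering loss into the encoder itself.

## The method

An encoder `f_θ : X → Z` maps samples `x_i ∈ R^D` to latent features
`z_i ∈ R^d`, trained (phase 1) with a reconstruction objective
`L_AE = Σ_i ‖x_i − f(x_i)‖²` — plain, denoising (dropout-corrupted input),
variational (negative ELBO), convolutional, or sequence-reversing LSTM,
depending on the data modality. Dense encoders are initialized by greedy
layer-wise denoising pretraining and end-to-end fine-tuning.

Phase 2 initializes K centroids `μ_j` on `Z` (k-means, Ward agglomerative or
a Gaussian mixture), soft-assigns every sample with a Student's-t kernel

    q_ij = (1 + ‖z_i − μ_j‖²/α)^(−(α+1)/2) / Σ_j' (1 + ‖z_i − μ_j'‖²/α)^(−(α+1)/2),  α = 1,

builds the self-sharpening auxiliary target

    p_ij = (q_ij²/f_j) / Σ_j' (q_ij'²/f_j'),   f_j = Σ_i q_ij,

and minimizes the combined loss `L = σ·KL(P‖Q) + (1−σ)·L_AE` with Adam,
propagating the closed-form gradients ∂L/∂z_i and ∂L/∂μ_j through the
encoder and the centroids. P is refreshed every `update_interval` steps;
training stops when fewer than `tol`% of samples change hard assignment
between consecutive refreshes.

Quality is scored with the standard external suite — unsupervised clustering
accuracy (best one-to-one cluster/class matching via the Hungarian
algorithm), NMI, Rand and adjusted Rand indices, homogeneity and
completeness — plus WCSS/Elbow curves over K and the generalizability ratio
`G = L_train / L_validation`.

Everything is testable offline: seeded generators plant unambiguous cluster
structure in tabular blobs, FPKM-like expression matrices with
signature-gene blocks, procedurally textured images and token corpora with
class-specific vocabularies.

## Worked example

Three Gaussian clusters planted in a 2-d latent space, embedded nonlinearly
in 50 dimensions, recovered by a stacked-denoising backbone with k-means
initialization and KLD hardening:

```r
library(deepclust)

ds <- make_blob_dataset(n_per_class = 200, n_clusters = 3, latent_dim = 2,
                        ambient_dim = 50, separation = 8, noise_sd = 1, seed = 1)
spec <- backbone_spec("stacked_denoising", layer_sizes = c(64, 32), latent_dim = 5)
model <- build_backbone(spec, input_shape = 50, seed = 1)
cfg <- deep_clustering_config(pretrain = TRUE, pretrain_epochs = 5, seed = 1)
fit <- fit_deep_clustering(model, ds$values, k = 3, config = cfg)

fit
#> <deep_clustering_fit>  K=3  n=600  steps=280  converged=TRUE
#>   generalizability G = 0.957
metrics_report(ds$labels, fit$labels)
#> Clustering quality:
#>   acc           0.9983
#>   nmi           0.9904
#>   ri            0.9978
#>   ari           0.9950
#>   homogeneity   0.9904
#>   completeness  0.9904
round(fit$loss_history, 4)
#>   iteration    L_AE  L_KLD combined pct_changed
#> 1         0  4.0533 0.1051   0.1051          NA
#> 2       140  8.2118 0.0933   0.0933      0.1667
#> 3       280 11.2036 0.0823   0.0823      0.0000
```

The run converged by the assignment-change rule (0% of points moved between
the last two target refreshes), the KLD hardening loss fell monotonically,
and 599 of 600 samples land in their generating cluster (ACC 0.998). `L_AE`
rises during hardening because the schedule σ = 1 optimizes the clustering
loss alone — exactly the trade-off the combined loss controls; pass
`sigma = 0.5` to `deep_clustering_config()` for joint training.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/deepclust.R generate --modality expression --out data/ --seed 1
Rscript inst/cli/deepclust.R cluster --data data/values.tsv --k 3 --mode joint --out run/ --seed 1
Rscript inst/cli/deepclust.R evaluate --labels run/labels.tsv --truth truth.tsv --out metrics.json
```

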