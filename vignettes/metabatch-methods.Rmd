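---
title: "metabatch: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metabatch: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`metabatch` treats batch correction as an adversarial representation
problem. An encoder $E$ compresses each sample's feature vector to a
latent code, a decoder $D$ reconstructs it, and a softmax classifier
tries to predict the batch from the code. The autoencoder minimizes

$$ L \;=\; \lambda_g\,\bigl(\mathrm{MSE}(X, D(E(X))) + r_g\bigr)
        \;-\; \lambda_d\,L_d \;+\; \lambda_v\,L_v $$

while the classifier simultaneously minimizes its cross-entropy $L_d$
on the same codes (alternating updates, one classifier step then one
autoencoder step per minibatch). The negative sign makes the autoencoder
seek codes from which the batch cannot be predicted.

Two regularizers protect the biology while the adversarial term removes
the batches:

* **Grouping reward $r_g$.** Users declare *reference groups*: sets of
  samples that are supposed to be similar (pooled QCs, spike-ins,
  technical replicates) and that span at least two batches. All samples
  are embedded to 2-D with UMAP, clustered with HDBSCAN, and
  $r_g = 1 - \frac{\#\text{same-group pairs sharing a cluster}}
  {\#\text{same-group pairs}} \in [0,1]$, zero at perfect co-clustering.
  Points labelled noise count as their own singleton clusters, so a
  reference sample lost in the noise always penalizes.
* **Variation loss $L_v$.** For every (reference group, batch, feature)
  with $\ge 2$ replicate samples, the coefficient of variation
  sd/mean of the *reconstructed intensities* is computed; $L_v$ is the
  mean. This directly counters the replicate-VC inflation that batch
  normalizers tend to introduce.

### Scales and positivity

Intensities are log10-transformed and standardized per feature before
PCA and training; the normalized output is obtained by de-standardizing
and exponentiating $D(E(X))$, which makes strictly positive output a
structural guarantee rather than a hope. PCA on the standardized matrix
means "variance explained" is correlation-scale, so a handful of
high-abundance ions cannot dictate the bottleneck width.

### Differentiability of the loss terms

Reconstruction, $L_d$ and $L_v$ are differentiated analytically
(including the chain through the inverse transform for $L_v$; the
gradients are verified against finite differences in the test suite).
$r_g$ is a function of a clustering and is therefore piecewise constant
in the model parameters: its gradient is zero almost everywhere, exactly
as if it were computed outside an autograd graph. It consequently acts
through monitoring, the reported aggregate loss and model selection, not
through the parameter updates, and is evaluated on the full data once
per epoch (`rg_every`) rather than per minibatch — for the optimizer the
two schedules are equivalent, and the coarser one bounds the UMAP cost.
The differentiable, distance-based alternative
(`grouping_term_distance()`: mean same-group pair distance over mean
all-pair distance in latent space) is provided as a metric for
comparison; it remains informative even when all replicates fall into a
single cluster, where the clustering reward saturates at zero.

## Tunables

| parameter | default | meaning / rationale |
|---|---|---|
| `min_relevant_intensity` | 1000 counts | lowest meaningful intensity; missing **and** sub-threshold cells are floored to it. The sub-threshold action is not prescribed anywhere; treating low values like missing unifies detection-limit censoring with explicit missingness and keeps the log transform defined. |
| `variance_ratio` | 0.9 | cumulative PCA explained-variance target that sizes the bottleneck; `latent_dim` overrides it for sweeps. |
| `lambda_g, lambda_d, lambda_v` | grid-searched, log-uniform on $[10^{-3}, 10]$ | relative term weights; no rescaling of $r_g$/$L_v$ against the reconstruction is attempted — balancing is delegated to the grid search. |
| `lr_ae, lr_cls` | 2e-3 (grid: log-uniform $[10^{-4}, 10^{-2}]$) | Adam learning rates. |
| `epochs` | 100 | desk-scale runs (seconds to minutes per run at a few hundred samples). |
| `batch_size` | 32 | small minibatches give enough update steps per epoch at typical sample counts. |
| `patience` | 5 epochs | consecutive classifier-loss increases that trigger `early_stop_classifier`. |
| `window` | 20 epochs | burn-in before the patience rule may fire. Adversarial training routinely drives $L_d$ up during the first epochs while reconstruction is still poor and then recovers; without a burn-in nearly every healthy run would abort. Chosen once from observing seeded synthetic runs, then fixed. |
| `collapse_ratio` | 1e-3 | output/input variance ratio under which the run stops as `early_stop_collapse` (near-constant decoder output trivially defeats the classifier while destroying the data). |
| `reconstruction` | `"mse"` | mean absolute error is available (`"mae"`) but is outlier-sensitive, a known failure mode of adversarial normalizers. |
| UMAP | `n_neighbors = 15`, `min_dist = 0.1`, 200 epochs, PCA init | fixed and seeded for reproducibility. |
| HDBSCAN | `min_cluster_size` = size of the smallest reference group | smaller clumps than the smallest declared group cannot be meaningful reference clusters. |

Model architecture: one leaky-ReLU hidden layer of bottleneck width on
each side of a linear bottleneck; linear softmax classifier on the
codes. Shallow on purpose — the bottleneck rule removes the main
capacity hyperparameter, and a full 10-run grid search completes in
about two minutes on one CPU at 200 × 60.

## The synthetic generator

`simulate_batches()` emulates a multi-batch benchmarking panel:
reference groups aliquoted from one master mix and re-measured in (a
subset of) every batch, plus batch-specific study samples. The
generative model is the standard multiplicative ion-suppression picture:

$$ \text{observed}_{ij} = \text{true}_{ij}\cdot
   \text{batchfactor}_{b(i),j}\cdot \text{noise}_{ij} $$

with log-normal true abundances (log10-mean 5, log10-sd 1, i.e. ion
counts spanning roughly 3–7 decades), per-(batch, feature) log-normal
batch factors (natural-log sd 0.8 by default — strong enough that a
probe classifier reaches >80% accuracy on the raw data), unit-mean
log-normal measurement noise at CV 0.1, and detection-limit censoring
below 1000 counts (≈2–3% of cells at the defaults). Defaults: 5 batches
× 40 samples (two reference groups in triplicate + 34 study samples) ×
60 features.

What it deliberately does **not** emulate: intra-batch temporal drift,
retention-time shifts, correlated feature blocks (adducts/isotopologues
of one compound), batch-specific missingness mechanisms, and
heteroscedastic electronic noise at the low end. A green test on this
generator therefore establishes that the machinery removes
*multiplicative, feature-wise, batch-constant* effects while preserving
replicate structure — not that it handles drift or structured artifacts;
for data with strong intra-batch drift a per-batch detrending should
precede this tool.

## Numerical choices

* **VC-inflation cutoff.** A feature counts as inflated when its mean
  replicate VC rises by ≥ 5%; the comparison uses a $10^{-9}$ relative
  epsilon so the mathematical "≥" is well defined in floating point.
  The fraction is computed over features (per-cell fraction attached as
  an attribute).
* **Constant features** are centered but not scaled (unit divisor)
  during preprocessing, and reported by `validate_inputs()`.
* **Degenerate clustering inputs**: fewer points than
  `min_cluster_size` yield all-noise labelings; an absent or
  single-member reference group makes $r_g = 0$ with a warning, so
  training degrades gracefully to a purely adversarial autoencoder.
* **Determinism.** Everything flows from explicit seeds (R RNG plus a
  seeded xorshift generator inside the C++ UMAP layout); runs are
  bit-reproducible single-threaded. The grid search parallelizes over
  whole runs only, never within a run.
* **Ties in model selection** (equal rank sums) break toward the higher
  between-batch replicate correlation.

## Design decisions taken where the design was open

* **Core numerical components are in-package.** The target environment
  provides no R packages for deep learning, UMAP or HDBSCAN, so the
  network (analytic gradients + Adam), the UMAP fuzzy-set/SGD layout and
  the HDBSCAN condensed-tree/excess-of-mass algorithm are implemented
  here. The HDBSCAN is validated in the tests as partition-identical to
  scikit-learn's implementation on seeded fixtures, including noise
  assignment; the gradients against finite differences.
* **$r_g$ on latent codes**, not on the reconstructed output: the codes
  are where the batch signal is actively being removed, and the
  clustering there is what the adversarial game reshapes.
* **Early-stop burn-in window.** See `window` above; the patience rule
  alone (any 5 consecutive increases) would abort healthy runs during
  the initial adversarial transient.
* **Model selection by rank sum** over the four evaluation criteria
  (higher between-batch replicate correlation, lower mean batch VC,
  lower VC-inflation fraction, probe accuracy closest to chance): a
  transparent aggregation of exactly the criteria used to compare
  normalization methods.
* **Ablation comparisons at convergence.** When comparing loss
  configurations (all terms vs $\lambda_v = 0$ vs
  $\lambda_d = \lambda_v = 0$), all arms get 200 epochs: an *underfit*
  plain autoencoder reconstructs mostly shared structure and scores
  spuriously well on replicate correlation through shrinkage; at
  convergence it returns to the input's correlation level and the
  contribution of the adversarial and variation terms becomes visible.
* **Criterion interpretation.** "5 batches × 40 samples" is read as 40
  samples per batch (200 total), matching the reference-group layout
  that makes two groups span every batch in triplicate.

## Known limitations

* $r_g$ influences selection and monitoring but not gradients; with
  data where clustering is the only useful signal (very subtle batch
  effects), the distance-based variant would be the natural term to
  optimize, and wiring it into the gradient is the obvious extension.
* Training is CPU-bound and scales as (samples × features × bottleneck)
  per step; a few thousand samples by a few thousand features is the
  practical desk-scale ceiling.
* Per-seed variability across random starts is real (as the ranking
  table of any grid search shows); the recommended workflow is always a
  grid search with selection, never a single run.
* The batch-mixing probe is a linear classifier; nonlinear residual
  batch structure can evade it.
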