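---
title: "Dual-constraint semi-supervised deep embedded clustering: methods"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-constraint semi-supervised deep embedded clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcssdec)
```

## The model

`dcssdec` clusters instances $x_i \in \mathbb{R}^d$ by jointly learning a
nonlinear embedding $z_i = f_\theta(x_i) \in \mathbb{R}^{d'}$ and a set of
cluster centroids $\mu_1, \dots, \mu_C$ in that embedding. Supervision, when
available, enters only as *soft pairwise constraints*: a **should-link** pair
is rewarded for sharing a cluster, a **shouldNot-link** pair is penalized for
doing so. Neither kind is ever enforced as a hard requirement, so noisy or
contradictory side information degrades gracefully.

### Soft assignment

Membership of instance $i$ in cluster $j$ uses a Student's-$t$ kernel on
embedded distance:

$$
q_{ij} \;=\;
\frac{\bigl(1 + \lVert z_i - \mu_j \rVert^2 / \alpha\bigr)^{-\frac{\alpha+1}{2}}}
     {\sum_{j'} \bigl(1 + \lVert z_i - \mu_{j'} \rVert^2 / \alpha\bigr)^{-\frac{\alpha+1}{2}}},
$$

with $\alpha = 1$ by default. Each row of $Q$ is a fuzzy membership
distribution.

### Self-training target

The target distribution sharpens $Q$ while normalizing by soft cluster
frequency $f_j = \sum_i q_{ij}$:

$$
p_{ij} \;=\; \frac{q_{ij}^2 / f_j}{\sum_{j'} q_{ij'}^2 / f_{j'}}.
$$

Dividing by $f_j$ discourages large clusters from absorbing everything. Note
that $P$ does **not** sharpen every row unconditionally: when cluster
frequencies are unbalanced, the frequency normalization can move a row's mass
*away* from its current argmax (e.g. for
$Q = \begin{pmatrix} 0.6 & 0.4 \\ 0.9 & 0.1 \end{pmatrix}$ the first row of
$P$ is $(0.429, 0.571)$). Sharpening is guaranteed only under balanced
frequencies, and the test suite asserts exactly that corrected property.

### Objective

With should-link set $S$, shouldNot-link set $S\mathbb{N}$, fuzzifier
$m > 1$, and trade-off weights $\gamma_1, \gamma_2$:

$$
J \;=\; \sum_{i,j} p_{ij} \log \frac{p_{ij}}{q_{ij}}
\;-\; \gamma_1 \sum_{(r,k) \in S} \sum_j q_{rj}^m q_{kj}^m
\;+\; \gamma_2 \sum_{(r,k) \in S\mathbb{N}} \sum_j q_{rj}^m q_{kj}^m .
$$

The KL term is self-training toward the sharpened target; the second term
rewards should-link pairs whose memberships agree; the third penalizes
shouldNot-link pairs whose memberships agree. The fuzzifier $m$ appears only
in the constraint terms. All logarithms are natural. Setting
$\gamma_1 = \gamma_2 = 0$ with no constraints recovers plain deep embedded
clustering exactly; the package tests verify this reduction is bit-identical.

## Training protocol

1. **Autoencoder pretraining.** A stacked autoencoder
   ($d$–500–500–2000–$d'$ by default, $d' = 10$) is pretrained greedily:
   each encoder/decoder layer pair is trained in isolation as a denoising
   autoencoder (dropout noise 0.2 on its input), then the full stack is
   fine-tuned end to end on the summed squared reconstruction error
   $\sum_i \lVert x_i - \hat x_i \rVert^2$ without noise. Internal layers
   use ReLU; the input-facing, embedding, and output layers are linear.
   Weights use Glorot-uniform initialization; optimization is Adam with
   learning rate 0.001. Each phase stops early when the relative per-epoch
   loss decrease falls below 0.001.
2. **Initialization.** The decoder is discarded. Centroids are initialized
   by K-means on the embedded data with 20 restarts, keeping the run with
   the lowest within-cluster sum of squares.
3. **Joint optimization.** Encoder weights and centroids are updated by
   mini-batch Adam on $J$, using hand-derived analytic gradients of the
   Student's-$t$ kernel (verified against central finite differences in the
   test suite). The target $P$ is recomputed on the full dataset every
   `update_interval` (default 140) batches. Constraint pairs contribute when
   both endpoints fall in the current batch, rescaled by
   (total pairs)/(pairs in batch) so the expected gradient matches the
   full-data objective; an alternative `pair_batch` mode samples constraint
   pairs directly each step.
4. **Stopping.** At each target refresh after the first, training stops when
   the fraction of instances whose hard label changed since the previous
   refresh is below `tolerance` (default 0.001). Hard labels break ties
   toward the lowest cluster index.

## Constraint generation

Given labels and a constraint ratio $\beta$, `generate_constraints()` draws
`round(beta * N)` unordered pairs uniformly without replacement from all
$\binom{N}{2}$ pairs (via a linear-index decode, so no candidate enumeration
is materialized), then splits them into should-link (labels agree) and
shouldNot-link (labels differ). Pairs are stored 1-based in memory and
written 0-based to tab-separated files with the header line `#i<TAB>j<TAB>type`
and `type` in `{SL, SNL}`.

## Synthetic data

`generate_blobs()` places $C$ Gaussian clusters at radius
$\mathrm{separation} \cdot \sigma / \sqrt{2}$ along random orthonormal
directions (QR decomposition of a Gaussian matrix), so every pair of centers
is $\mathrm{separation} \cdot \sigma$ apart; it requires $C \le d$. Cluster
sizes are balanced unless an `imbalance` vector is given, rows are shuffled
deterministically, and labels are 0-based. This emulates the *geometry* of a
clustering benchmark — controllable separation, known ground truth — not the
manifold structure of natural images; `generate_toy_images()` adds simple
glyph images (bars, disks, crosses) when a pixel-like input is wanted.
Neither generator attempts to reproduce any real dataset.

## Numerical choices

- Denominators in the target distribution are guarded with `1e-12`; the KL
  term treats $0 \log 0 = 0$ and raises an error (rather than returning
  `Inf`) when $p_{ij} > 0$ with $q_{ij} = 0$.
- `tolerance` is accepted on $(0, 1]$; `tolerance = 1` stops at the first
  refresh check, which is useful for smoke tests.
- Pairwise squared distances use the BLAS outer-product identity with
  negative values clamped to zero.
- All randomness flows through a master seed expanded with `derive_seed()`;
  every public entry point restores the caller's `.Random.seed`.
- Presets in `dcssdec_presets()` record published tuned hyper-parameter
  sets for reference; they do not download or require the corresponding
  datasets.

## Limitations

- The optimizer is plain R; it is intended for datasets up to a few
  thousand instances, not 70k-image benchmarks.
- The method assumes the number of clusters $C$ is known.
- Constraint quality matters: heavily contradictory supervision with large
  $|\gamma|$ can distort the embedding, since constraints are soft
  objective terms, not filtered.
- Convergence is to a local optimum; the K-means restart count and the
  autoencoder seed both influence which one.

## A small worked example

```{r example, eval = FALSE}
ds <- generate_blobs(synthetic_spec(n_samples = 300, n_features = 20,
                                    n_clusters = 3, separation = 6,
                                    seed = 2))
ae <- pretrain(ds$X, autoencoder_spec(20, layer_dims = c(20, 32, 16, 5),
                                      pretrain_epochs = 15,
                                      batch_size = 128, seed = 3))
cs <- generate_constraints(ds$labels, beta = 1, seed = 4)
res <- dcssdec_train(ds$X, ae, cs,
                     train_config(n_clusters = 3, batch_size = 128,
                                  update_interval = 30,
                                  max_iterations = 600, seed = 5))
evaluate_clustering(ds$labels, res$labels)
```
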