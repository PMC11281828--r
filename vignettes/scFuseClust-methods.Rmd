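---
title: "scFuseClust: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scFuseClust: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scFuseClust clusters single-cell RNA-seq count matrices by fusing two
complementary low-dimensional representations of the same cells and refining
the result with deep embedded clustering. This vignette explains the model,
the parameters that matter, the numerical choices, and what the built-in
simulation can and cannot tell you about behaviour on real data.

## The model

**Preprocessing.** Cells and genes with zero total counts are removed. A
standard dispersion-based criterion (mean-binned normalized dispersion on
log-normalized expression; a Seurat-v3-style variance-stabilizing score is
available via `hvgFlavor = "vst"`) selects `nHVG` highly variable genes
(default 2500, capped at the gene count). The selected genes are then
**ordered by total raw counts, descending** — this ordering is a contract the
loss re-weighting below depends on. Each cell is scaled to the median library
size and log1p-transformed; genes are z-scored to mean 0, variance 1
(`Xbar`). A directed 15-nearest-neighbour graph over cells is built with
cosine distance and Gaussian-kernel edge weights
\(\exp(-d^2/2\sigma^2)\); its max-symmetrized, self-looped, symmetrically
normalized form \(\hat A = D^{-1/2}(A_{sym}+I)D^{-1/2}\) drives the graph
encoder.

**Low-expression-weighted ZINB likelihood.** scRNA-seq counts are modelled as
zero-inflated negative binomial: a point mass at zero with probability
\(\pi\) mixed with NB(\(\mu,\theta\)). Because lowly expressed highly
variable genes often carry the signal for rare cell types but contribute
little to a plain reconstruction loss, the likelihood is evaluated not on
\(X\) but on \(X'\): with genes ordered by expression and
\(k=\lfloor \text{tailorRate}\cdot m\rfloor\), columns \(j\le k\) are left
unchanged and columns \(j>k\) are multiplied by `lossRate`. Defaults are
tailorRate = 0.9 and lossRate = 2, so the lowest-expression tenth of the
HVGs counts double in the loss. The data themselves are never modified —
only the likelihood sees \(X'\), and the zero/nonzero decision is always
taken on the original counts. The NB density is computed through log-gamma
functions, so non-integer \(X'\) (non-integer loss rates) is well defined.

**Denoising autoencoder (DAE).** The encoder takes \( \bar X + \epsilon\)
with \(\epsilon \sim N(0, 0.01)\) (training only) through MLP layers of
widths 256, 64, 16; the decoder mirrors them (64, 256). Three linear heads
on the decoder output produce \(\pi = \mathrm{sigmoid}(DW_\pi)\),
\(\mu = \mathrm{sf}_i \cdot \exp(DW_\mu)\), and
\(\theta = \exp(DW_\theta)\). The \(\mu\) head is scaled per cell by the
library-size factor (library size / median library size) so reconstructed
means match the raw counts — the standard ZINB-autoencoder construction. Hidden activations are ReLU; the latent layer is
linear.

**Graph autoencoder (GAE).** Three graph-convolution layers
\(Z^{(l)} = \tanh(\hat A Z^{(l-1)} W^{(l-1)})\) with widths mirroring the
DAE encoder (256, 64, 16). The first linear reduction is shared with the DAE
(`shareReduction = TRUE`). The decoder reconstructs the graph by
\(\tilde A = \mathrm{sigmoid}(ZZ^\top)\), trained with mean squared error
against the **weighted symmetrized KNN adjacency without self-loops**: the
self-looped normalized \(\hat A\) is a propagation operator, not a
reconstruction target, and reconstructing the raw graph keeps the two roles
distinct.

**Attention fusion.** Two fusion blocks of eight dot-product attention heads
each act at the 256- and 64-wide encoder levels. Queries come from the GAE
embedding \(Z^l\), keys and values from the DAE embedding \(E^l\); per head
\(a_m = \mathrm{softmax}(Q_m K_m^\top)\) (the dot product is **unscaled** by
default — the method is defined without the transformer's temperature;
`scaledAttention = TRUE` enables the \(1/\sqrt{d_k}\) factor), and the block output is
\(W_o\,\mathrm{Concat}(a_1V_1,\dots,a_8V_8) + E^l\). The fused \(R^1\) feeds
the next encoder layer; the second fused output \(R^2\) (64-dimensional) is
the clustering representation. Per-head projection widths are the block
width divided by the head count — the only shape consistent with the
concatenation-plus-residual form.

**Training.** Phase 1 minimizes
\(L_{train} = L_{ZINB} + r_1 L_{graph}\) (both mean-reduced; \(r_1 = 0.1\))
with Adam (learning rate 0.001, global gradient L2-norm clipped at 3).
Phase 2 initializes one centroid per Leiden community detected on a KNN
graph of \(R^2\) (modularity objective, resolution 1), then minimizes
\(L = L_{KL} + r_2 L_{train}\) (\(r_2 = 0.1\)), where
\(q_{ij} = (1+\|z_i-\mu_j\|^2/\alpha)^{-1}\) normalized per cell
(\(\alpha = 1\)), \(p_{ij} \propto q_{ij}^2 / \sum_i q_{ij}\) renormalized
per row, and \(L_{KL} = \sum_{ij} p_{ij}\log(p_{ij}/q_{ij})\). The target
\(P\) is recomputed every `updateInterval` (10) epochs; training stops early
when fewer than 1/1000 of the cells change hard label between consecutive
target updates. All three losses stay live during fine-tuning — the
architecture is fixed after pretraining, but the network weights keep
training alongside the centroids rather than being frozen.

**Adaptive centroid pruning.** At every target update, centroids whose hard
assignment falls below `minCells` are removed, weakest first, with cells
reassigned after each removal; the effective number of clusters K can only
shrink. The default `minCells = 1` prunes exactly the empty centroids — the
most conservative notion of an unstable cluster, and the only one that never
discards genuine signal. A fractional `minCells` (share of n) is available
for aggressive pruning. Two honest caveats from our experiments: (i) with
the default resolution the Leiden initialization on the pretrained embedding
typically already finds the correct number of well-separated clusters, so
pruning is a safety net rather than the main mechanism; (ii) if the
initialization is deliberately over-resolved, DEC refinement stabilizes the
over-partition rather than merging it — the target distribution reinforces
whatever assignment currently holds — so exact convergence of K to the true
value under over-initialization is not guaranteed, and the tests assert
monotone non-increase plus cluster purity instead.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tailorRate` | 0.9 | fraction of high-expression HVG columns left unscaled in the loss |
| `lossRate` | 2 | loss multiplier for the trailing low-expression columns |
| `nHVG` | 2500 (capped) | highly variable genes kept |
| `kNeighbors` | 15 | KNN graph degree |
| `r1`, `r2` | 0.1 | loss-balance weights |
| `lr`, `clipNorm` | 0.001, 3 | Adam learning rate, global gradient-norm clip |
| `noiseSD` | 0.1 | input noise s.d. (variance 0.01) |
| `nHeads` | 8 | attention heads per fusion block |
| `alpha` | 1 | Student's-t degrees of freedom |
| `leidenResolution` | 1 | initialization granularity |
| `minCells` | 1 | pruning threshold (fraction of n if < 1) |
| `earlyStopTol` | 0.001 | label-change fraction that stops fine-tuning |
| `pretrainEpochs`, `finetuneEpochs` | 30, 60 | phase lengths (early stop usually ends fine-tuning after 10–20 epochs) |

Epoch counts are convergence choices verified on the built-in simulation at
its default size (500 cells, 200 genes): the pretraining loss plateaus well
before 30 epochs and fine-tuning reliably early-stops. Larger or harder data
may need more.

Ablation switches `noAttention` (fusion blocks replaced by an MLP on the
concatenated embeddings), `noGAE` (queries fall back to the DAE embedding;
no graph loss), `noDAE` (topological path only; no ZINB loss), and
`noTailor` (`lossRate = 1`, the standard ZINB loss) remove one component
each while keeping everything else fixed.

## The synthetic-data generator

`simulateCounts()` draws ZINB counts with cluster-specific mean profiles:
log-normal baseline gene means, `markersPerCluster` marker genes per cluster
elevated by `exp(logFC)`, a fraction `lowExprFraction` of markers placed at
a low absolute baseline (so they are highly variable *and* lowly expressed —
exactly the regime the re-weighted loss targets), per-cell log-normal
library factors, NB noise with gene-wise dispersion `dispersion`, and
uniform zero-inflation `dropoutPi`. Defaults (500 cells, 200 genes, 3 equal
clusters, logFC = 2, dispersion = 2, dropoutPi = 0.1, half the markers
low-expression) describe a well-separated recovery benchmark: strong marker
signal a practitioner would call clearly resolvable cell types.
`injectDropout()` additionally zeroes a fixed fraction of the *nonzero*
entries (floor convention, so the corruption count is deterministic); the
sampling universe for "randomly set expression values to zero" is a
documented choice — zeroing already-zero entries would be a no-op.

What the simulation does **not** emulate: batch effects, doublets, ambient
RNA, gene-gene correlation beyond the cluster means, and realistic
gene-specific dropout-expression relationships (zero inflation is uniform).
Passing the recovery tests therefore demonstrates the machinery is correct
and the method recovers planted, well-separated structure; it does not
certify performance on real tissues.

## Numerical choices

- All networks run on a reverse-mode autodiff tape implemented in the
  package (`R/tape.R`, hot kernels in `src/ops.cpp`); every primitive and
  every fused composite is validated against central finite differences in
  the test suite.
- \(k=\lfloor \text{tailorRate}\cdot m\rfloor\) and
  floor-based dropout counts: deterministic integer conventions.
- `eps = 1e-10` inside ZINB logs; \(\theta\) clamped to \([10^{-4}, 10^4]\)
  and exponent arguments to \([-15, 15]\); z-score denominators of
  zero-variance genes are guarded (the gene maps to 0) with a warning.
- Gaussian-kernel bandwidth: per-cell local scaling (distance to the k-th
  neighbour), with a global-median alternative; the KNN graph keeps kernel
  weights (`binarize = FALSE`) — both are free choices of this
  implementation, exposed in the configuration.
- The directed KNN graph is symmetrized by the elementwise maximum before
  normalization, the weakest assumption that yields a symmetric \(\hat A\).
- Hard labels are `argmax` of Q with first-index tie-breaking, so runs are
  bit-reproducible under a fixed seed (the seed covers simulation, weight
  initialization, input noise, and Leiden refinement).
- The KL objective is summed over cells; the ZINB term is averaged per
  batch (`reduction = "mean"`), so its weight does not grow with the matrix
  size. Both reductions are exposed.

## Known limitations

- Full-batch training with dense \(n \times n\) attention and graph
  reconstruction: memory and time grow quadratically with the cell count.
  Practical on thousands of cells, not hundreds of thousands.
- The Leiden initialization inherits modularity's behaviour on KNN graphs:
  on diffuse geometric blobs it over-partitions; the pipeline relies on the
  pretrained embedding being compact per cluster (which the fused training
  produces) for the initial K to be sensible.
- Only the dispersion-based and vst HVG flavours are implemented, and no
  batch correction or QC beyond empty-row/column filtering is performed.
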