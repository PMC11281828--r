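# scFuseClust

Deep embedded clustering of single-cell RNA-seq count matrices, for
researchers who need cell-type inference **without presetting the number of
clusters** and who care about the signal carried by **lowly expressed highly
variable genes**.

## The method

Most clustering pipelines let a handful of highly expressed genes dominate
the representation. scFuseClust counteracts that in three ways:

1. **A low-expression-weighted ZINB autoencoder.** Counts are modelled as
   zero-inflated negative binomial, X ~ π δ₀ + (1−π) NB(μ, θ). The
   reconstruction likelihood is evaluated on a re-weighted matrix X′: with
   genes ordered by total expression and k = ⌊tailorRate · m⌋,

       X′ᵢⱼ = Xᵢⱼ            if j ≤ k
       X′ᵢⱼ = lossRate · Xᵢⱼ  if j > k

   (defaults tailorRate = 0.9, lossRate = 2), so the lowest-expression tenth
   of the highly variable genes counts double in the loss while the data
   themselves are untouched. A denoising MLP autoencoder (widths
   256-64-16-64-256, Gaussian input noise of variance 0.01) fits per-entry
   (π, μ, θ) through sigmoid/exp heads with library-size-scaled means.

2. **A graph autoencoder over the cell-cell KNN graph.** Three GCN layers
   Z⁽ˡ⁾ = tanh(Â Z⁽ˡ⁻¹⁾ W) over the self-looped, symmetrically normalized
   15-NN graph (cosine distance, Gaussian-kernel weights), decoded by
   Ã = sigmoid(ZZᵀ) under a mean-squared-error graph loss.

3. **Multi-head attention fusion + deep embedded clustering.** Two blocks of
   eight dot-product attention heads fuse the topological embedding
   (queries) with the denoising embedding (keys/values, residual); the fused
   64-dimensional representation R² is clustered DEC-style: Student's-t soft
   assignments qᵢⱼ = (1+‖zᵢ−μⱼ‖²)⁻¹ (normalized) against centroids seeded by
   **Leiden community detection** (no preset K), sharpened by
   pᵢⱼ ∝ qᵢⱼ²/Σᵢqᵢⱼ under a KL loss, with under-populated centroids pruned
   adaptively. Training: L_train = L_ZINB + 0.1·L_graph, then
   L = L_KL + 0.1·L_train (Adam, lr 0.001, gradient-norm clip 3, early stop
   when < 1/1000 of cells change label between target updates).

Everything runs on a compact reverse-mode autodiff tape implemented in the
package (R with RcppArmadillo kernels for the attention heads); gradients
are verified against finite differences in the test suite. See
`vignettes/scFuseClust-methods.Rmd` for assumptions and design choices.

## Worked example

```r
library(scFuseClust)

# ZINB counts with 3 planted, well-separated clusters
sce <- simulateCounts(nCells = 500, nGenes = 200, kClusters = 3, seed = 11)

res <- scfPipeline(sce, scfConfig(seed = 11))
res$fit
#> ScfFit: 500 cells, 3 clusters (initialized at 3 by Leiden)
unlist(res$metrics)
#> silhouette        ari        nmi
#>  0.7972956  1.0000000  1.0000000
```

The fit recovers the 3 planted clusters exactly (ARI = NMI = 1): the Leiden
initialization on the pretrained fused embedding proposes 3 centroids and
DEC refinement confirms them; the silhouette of ~0.8 on the 64-dimensional
embedding reflects compact, well-separated groups. `clusterLabels()`,
`cellEmbedding()` and `trainHistory()` access the labels, the clustering
representation, and the per-epoch losses / effective-K / label-change log.
`writeRun()` writes labels.tsv, embedding.csv, history.jsonl and the
resolved config; a command-line wrapper with `simulate | run | eval`
subcommands lives at `inst/cli/scfuseclust.R`.

Ablation arms — `scfConfig(noAttention = TRUE)`, `noGAE`, `noDAE`,
`noTailor` — disable one component each, and
`injectDropout(sce, rate, seed)` stresses the model with manual dropout.

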