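---
title: "Sparsely connected autoencoders for single-cell omics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparsely connected autoencoders for single-cell omics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scSCA)
```

## The model

A sparsely connected autoencoder (SCA) is a single-hidden-layer autoencoder
whose hidden nodes are *interpretable by construction*: each node stands for
a metafeature — a transcription factor (TF), a miRNA, or a cell cluster —
and is wired only to the input features that metafeature governs. Writing
$M \in \{0,1\}^{K \times P}$ for the connectivity mask over $K$ metafeatures
and $P$ input features, the model is

$$h = \mathrm{relu}\big((M \circ W_e)\,x + b_e\big), \qquad
  \hat{x} = (M^\top \circ W_d)\,h + b_d,$$

with $\circ$ the elementwise product. Training minimizes mean squared
reconstruction error. Because the mask multiplies the weights in the forward
pass, gradients flow only through unmasked entries, and masked positions are
exactly zero after every update — not merely small. This is the property the
whole toolkit rests on: the activation of node $k$ can only reflect the
expression of its own target set, so the hidden layer is a biologically
addressable summary of the input.

Two orientations of the same machine cover the package's use cases:

* **Pseudo-bulk** (`pseudobulk_replicates()`): training samples are genes,
  input features are cells, and each hidden node is one cluster, connected
  to its member cells. The activation of gene $g$ at node $c$ is a denoised
  aggregate of $g$'s expression over cluster $c$ — a pseudo-bulk value.
  Since the clustering partitions the cells, mask rows are disjoint and
  every cell column carries exactly one 1.
* **Metagenes** (`metagene_matrix()`): training samples are cells, input
  features are the TF/miRNA target genes, and each hidden node is one
  regulator. The activation of cell $i$ at node $t$ is the metagene value
  of regulator $t$ in that cell.

Repeated runs from independent initializations ("permutations") are the
second pillar. Each run lands in a slightly different optimum; for
pseudo-bulks the per-run hidden layers are kept side by side as
*pseudo-replicates* (20 runs by default), giving clusters the replication
structure that bulk-style analyses need. For metagenes the runs are
*cumulatively summed* (100 by default): informative metafeatures accumulate
signal coherently across runs while noise stays near background, so the
between-population contrast of planted regulators grows with the number of
runs. A `mean` flag divides by the run count for scale-sensitive downstream
use; the plain sum is the default because it is the canonical form of the
procedure.

## Training choices

The training loop is deliberately plain, and every choice is exposed in
`sca_config()`:

* **Activation** relu (default) or sigmoid; the decoder is linear. Relu
  makes hidden activations nonnegative, which is what licenses treating
  pseudo-bulk activations as count-like values that CPM normalization and
  log transforms accept.
* **Loss and optimizer**: mean squared reconstruction error, Adam with
  learning rate $10^{-3}$, exactly `n_epochs` epochs (1000 in the reference
  setting), no early stopping.
* **Input scaling**: counts are transformed by $\log(1+x)$ and min-max
  scaled to $[0,1]$ per input feature. Constant features map to zero and
  carry no gradient. Pre-normalized matrices can opt out with
  `scale_input = FALSE`.
* **Initialization**: weights start from a *nonnegative* half-Glorot draw,
  $U(0, \sqrt{6/(P+K)})$, masked. With nonnegative inputs and relu hidden
  units, a sign-symmetric initialization admits mirrored optima in which a
  hidden node *anti*-correlates with the aggregate expression it should
  summarize (the decoder absorbs the sign), and nodes can die outright; in
  our measurements a symmetric draw produced anticorrelated or dead nodes
  in roughly 40% of seeds on a one-cluster problem. Starting in the
  nonnegative orthant selects the interpretable basin without constraining
  training — weights remain free to change sign.
* **Batching**: full-batch up to 2048 samples (every matrix in this
  package's intended regime), mini-batches of 128 with per-epoch shuffling
  beyond that. Full-batch training plus a fixed seed makes every run
  bitwise reproducible; run $r$ of a multi-run experiment uses seed
  `base_seed + r`, so runs are order-independent and individually
  reconstructible.
* **Degenerate inputs**: metafeatures with no surviving target are dropped
  when the mask is built; features connected to nothing are dropped too
  (`drop_unconnected`), so the model never reconstructs inputs it cannot
  see. A non-finite loss aborts with the epoch number rather than returning
  garbage.

## Preprocessing and downstream conventions

The preprocessing filters mirror standard single-cell practice: a gene is
*present* in a cell when supported by at least 3 UMIs (a threshold that
moderates UMI sequencing errors); cells need 250 present genes to survive
(400 for ATAC-derived gene activity); and the informative-gene panel is the
2500 most variant of the 5000 most expressed genes, computed on raw counts
— totals first, then variance among the survivors, ties broken by row
order. Cells are filtered before genes are selected; reversing the order
changes the result and is covered by a regression test.

Pseudo-bulk profiles are compared after log2CPM (pseudocount 1, so zeros
stay zero) and row-mean centering, and similarity is column-wise Pearson
correlation over the shared features, taken in sorted order with Ensembl
version suffixes stripped. Zero-variance profiles yield `NA` entries with a
warning, never a silent zero. Cross-experiment cluster matching
(`best_match()`) is row-directional — each query cluster points at its best
reference column — with ties within $10^{-12}$ flagged ambiguous rather
than broken; a `mutual` flag reports reciprocal best hits. Cell-type
assignment uses UPGMA (Euclidean distance, average linkage) over profile
columns, delegated to `stats::hclust` and checked in the test suite against
a brute-force implementation of the agglomeration rule.

For scATAC data, peak regions are assigned to every gene locus they overlap
by at least 1 bp, strand ignored, with no promoter extension by default
(`extend_upstream` is available but 0 keeps the gene body literal); a
multi-gene region contributes its full count to each gene. BED input is
0-based half-open and GTF 1-based inclusive; all interval logic converts at
the boundary so a single convention (0-based half-open) rules internally.

## What the simulator emulates — and what it does not

`simulate_counts()` draws the minimum structure the method's claims need:
cell types with distinct expected profiles, TF-driven gene modules
(per-type activity multipliers on disjoint target blocks, plus a uniform
null module), negative-binomial counts, log-normal library sizes, and
independent dropout. The reference design — five types of 150 cells, 800
genes, one 40-gene module per type at six-fold activation, baseline mean 2,
NB dispersion 2, 30% dropout, library spread 0.3 — was chosen once as a
realistic mid-depth droplet-style dataset and is the package's standing
benchmark; `simulate_paired_experiments()` derives from it the
five-type/three-type pair with a known cross-experiment correspondence,
and `simulate_atac_fixture()` builds a toy genome whose region-to-gene
assignments are known by construction.

The simulator does **not** emulate batch effects, doublets, ambient RNA,
gene-gene correlation beyond module structure, or depth-dependent dropout.
Passing the recovery benchmarks therefore shows that the implementation
faithfully executes the method under the generative assumptions the method
itself makes — not that the method is robust to every artifact of real
data.

## Benchmark sizes and numerical tolerances

The validation suite runs the full pipelines at reduced but honest sizes,
chosen so the whole suite completes comfortably on a laptop core: 20
pseudo-bulk runs of 200 epochs on the 800-gene/750-cell design for
recovery and cross-experiment matching, and 25 metagene runs of 200 epochs
on a 500-gene/300-cell three-type design for clustering recovery (Adjusted
Rand Index against the planted partition) and signal accumulation
(between/within F-ratio of planted metafeatures, 1 run vs 25). Exact
invariants are asserted tightly: CPM column sums within $10^{-6}$ of
$10^6$, centered row means within $10^{-9}$ of zero, masked-input
insensitivity within $10^{-12}$ (measured exactly 0), and count
conservation of the summing pseudo-bulk exactly. `scripts/acceptance.R`
recomputes all of these from scratch at any seed.

## Known limitations

* Hidden nodes compete only within their target sets; heavily overlapping
  target sets can split signal between correlated nodes, which the
  cumulative sum alleviates but does not remove.
* The pseudo-bulk orientation assumes the clustering is a partition; soft
  or overlapping cluster assignments are out of scope.
* `kmeans_convenience()` is a deliberately simple k-means++ wrapper for
  self-contained analyses, not a replacement for graph-based single-cell
  clustering.
* HDF5/10x `.h5`, loom, and BAM/fragment inputs are not read; counts come
  in as dense CSV/TSV or MTX triplets.
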