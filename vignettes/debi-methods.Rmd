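---
title: "Differentially expressed biclusters: model, algorithm and design notes"
author: "debi package"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Differentially expressed biclusters: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debi)
```

## The problem and the model

Standard clustering assigns every gene to one cluster and assumes the
cluster behaves coherently across *all* samples. Many transcriptional
programs, however, are active only in a subset of conditions, and a gene
can participate in several programs. Biclustering addresses this by
finding submatrices — a gene subset together with a sample subset — in
which expression is coherent.

`debi` implements the DeBi algorithm, which defines a bicluster by two
requirements:

1. **Homogeneity.** Every gene in the bicluster is strongly (up- or
   down-) regulated across *all* the bicluster samples.
2. **Differential expression.** Every gene in the bicluster is
   significantly more often regulated inside the bicluster samples than
   outside, as judged by a Fisher exact test.

The algorithm operates on a binarized matrix and runs in three steps:
seed discovery by maximal frequent gene-set mining, seed
extension/pruning by per-gene exact tests, and overlap filtering. A
fourth component selects the significance level by a
randomization-normalized score.

### Binarization

Input values are taken to be log2 expression ratios. For a fold-change
cut-off $c > 1$ the up-regulation indicator matrix is
$E^u_{ij} = \mathbf{1}[e_{ij} \ge \log_2 c]$, and the down-regulation
matrix analogously with $e_{ij} \le -\log_2 c$. The default is $c = 2$;
published analyses of the yeast compendium use $c = 1.58$. Since no
convention for the input scale is universal, the choice "values are
log2 ratios" is explicit and a `linear = TRUE` flag log2-transforms
linear-scale input first. Missing values binarize to 0: absence of
evidence of regulation, not imputed. Matrices that are already 0/1
(e.g. gene-set membership matrices) bypass binarization via
`prebinarized = TRUE` / `as_binary_matrix()`.

### Seed discovery

The *support* of a gene is the fraction of samples in which its
indicator row is 1; the *phenotype vector* $C_v$ of a gene set is the
element-wise AND of its rows, and the set's support is the fraction of
1s in $C_v$. A gene set is $(c_1, c_2)$-frequent when its support
clears $c_1$ and its cardinality is at least $c_2$, and *maximal
frequent* when no strict superset is frequent. Anti-monotonicity —
every subset of a frequent set is frequent — makes the lattice
prunable.

`mine_maximal_frequent()` performs a depth-first traversal of the
set-enumeration tree over genes ordered by decreasing support, prunes
infrequent extensions, and verifies full maximality of each candidate
against every remaining gene. Supports are compared as integer counts
(a support exactly equal to the threshold counts as frequent), which
avoids floating-point ties on rationals $k/m$. `brute_force_maximal()`
is the definitional exhaustive implementation, kept as an independent
oracle; the test suite checks set-for-set equality between the two on
hundreds of random matrices.

`discover_seeds()` applies the miner iteratively. The first threshold
is the largest single-gene support; all maximal frequent sets found
become seeds (their phenotype vectors frozen from the original matrix)
and their genes are removed from the working matrix. The next threshold
is the largest remaining support strictly below the previous one — the
laziest strictly decreasing schedule that guarantees progress; a gene
whose support equals a visited threshold but which joined no seed can
still join sets at lower thresholds. The loop stops below
`min_support` (default 0.05, user-adjustable) or when no genes remain.
Seeds are therefore pairwise disjoint in their genes. The default
minimum cardinality is $c_2 = 2$: a single-gene "set" is a trivial
bicluster.

### Extension and pruning

For each seed, every gene of the matrix is tested against the seed's
phenotype vector with a Fisher exact test on the 2x2 table of (gene
bit) x (phenotype bit) counts. The implementation uses the *one-sided*
over-representation tail (hypergeometric upper tail): although the full
Fisher test is two-sided, a two-sided gate would admit genes
significantly *depleted* in the bicluster samples, contradicting the
homogeneity requirement; the two-sided variant remains available through
`stats::fisher.test` for users who want it. Genes with $p < \alpha$ are
added, seed genes with $p > \alpha$ removed; the boundary case
$p = \alpha$ (possible with exact rational p-values, probability zero in
practice) changes nothing. The phenotype vector is never recomputed:
the bicluster's sample set is the seed's phenotype support, and a second
extension pass with the same $C_v$ is a no-op (idempotence, tested).

Because the p-value is monotone in the two margins — decreasing in
$\sigma_{1,IN}$ (gene 1s inside the bicluster samples) at fixed
$\sigma_{1,OUT}$, increasing in $\sigma_{1,OUT}$ at fixed
$\sigma_{1,IN}$ — two precomputed scalar cut-offs
(`compute_cutoffs()`) let the extension skip most genes without
computing their p-value: a gene is only tested when
$\sigma_{1,IN} > \min\sigma_{1,IN}$ and
$\sigma_{1,OUT} < \max\sigma_{1,OUT}$; every skipped gene provably has
$p > \alpha$. Degenerate phenotype vectors (all ones or all zeros) have
no contrast and yield $p = 1$ by convention.

### Overlap filtering

The size of a bicluster is genes x samples, and the overlap area of two
biclusters is shared genes x shared samples. `filter_overlap()` visits
biclusters largest-first (ties broken by discovery order, for
determinism) and deletes any bicluster whose overlap with an
already-kept one strictly exceeds $L$ times its own size — "exceeds" is
read strictly, so $L = 1$ removes only exact containments with equal
area. Up- and down-regulation biclusters are concatenated before
filtering, so the two directions compete in one pool. The conventional
default is $L = 0.5$; benchmark comparisons use $L = 0.25$.

### Choosing alpha

The raw score of a bicluster is $I_v = -\sum_g \ln p_g$ over its
retained genes. $I_v$ grows with bicluster size, so it is normalized by
a randomization estimate of its null expectation: 500 (by default)
random phenotype vectors with the same number of 1s are drawn as
uniform sample subsets without replacement, the genes' p-values against
each are computed, and $E[I_v]$ is the mean of the resulting random
scores. The normalized score is $NI_v = I_v / E[I_v]$ and the total
score of a run is $CS = \sum_v NI_v$. If $E[I_v] = 0$ (every random
p-value is 1, which only happens for signal-free all-ones gene rows)
$NI_v$ is defined as 0 with a warning — such a bicluster carries no
information.

`select_alpha()` runs the pipeline once per candidate $\alpha$ and
returns the maximizer of $CS$, ties going to the smaller $\alpha$; when
every candidate produces zero biclusters the largest $\alpha$ is
returned with a warning. The default grid is
$\{10^{-2}, 10^{-4}, 10^{-8}, 10^{-16}, 10^{-32}, 10^{-64}, 10^{-100}\}$:
$CS$ varies slowly in $\log \alpha$, and the 7-point grid costs a
fraction of the dense $10^{-2} \ldots 10^{-100}$ grid
(`alpha_grid(full = TRUE)`) while selecting the same neighborhood in
all cases we examined. Binarization and seed mining do not depend on
$\alpha$, so they are computed once and shared across the grid. The RNG
is reset to the run seed at the start of each $\alpha$'s scoring pass,
which makes the selection invariant to grid order and every run
reproducible end to end — two runs with the same configuration and seed
produce byte-identical output files.

## The synthetic benchmark

`generate_scenario()` emulates the classic implanted-bicluster design:
a zero background (log2 scale) with blocks placed along the diagonal.

* **Noise scenario** (default): a 100 x 50 matrix with ten
  non-overlapping 10 x 5 blocks; i.i.d. Gaussian noise with standard
  deviation `noise x level` is added to every cell.
* **Overlap scenario**: a 100 x 100 matrix with ten 10 x 10 blocks in
  which consecutive blocks share `overlap_degree` genes and samples
  (shift `10 - d`), noise-free.
* **Models**: *constant* blocks sit at `level` (default 2.0, i.e.
  4-fold up-regulation); *additive* blocks add distinct row and column
  offsets in steps of 0.1 so expression varies over the conditions.
  Offsets are non-negative, so every additive block cell stays above
  the $\log_2 2 = 1$ threshold — a threshold method could not recover
  the truth otherwise, so this is a property of the benchmark design,
  not a convenience.
* A `binary = TRUE` mode emits the 0/1 matrix directly with per-bit
  flip probability `noise`, for studying the miner in isolation.

What the generator does **not** emulate: correlated noise, missing
values, sample-specific scaling, down-regulated blocks mixed with
up-regulated ones, and realistic background expression structure. A
perfect recovery score on these scenarios therefore demonstrates the
pipeline's correctness on its own model assumptions, not performance on
real microarray data. At the benchmark noise levels (0–0.10 of the
block level, i.e. sd up to 0.2 against a margin of 1 log2 unit)
binarization flips essentially no bits; larger noise levels do degrade
the binary matrix and recovery with it.

Two scores compare a found set against the implanted truth:

* `prelic_recovery()` — for each true bicluster, the best Jaccard
  similarity of gene sets over the found biclusters, averaged over
  truth. It ignores the number of found biclusters; swapping the
  arguments gives the relevance orientation.
* `hochreiter_consensus()` — Jaccard similarities on (gene, sample)
  cell sets, an exact maximum-weight one-to-one assignment between the
  two collections (weighted bipartite matching via igraph; a greedy
  fallback exists for collections beyond a thousand biclusters), and
  the assigned sum divided by the size of the larger collection, which
  penalizes both over- and under-segmentation. Two empty sets score 1;
  exactly one empty set scores 0.

`run_benchmark()` ties generator, pipeline and scores together, one row
per scenario and replicate, with per-replicate seeds derived from the
base seed.

## Numerical and design choices

* Support comparisons are on integer counts with an absolute epsilon of
  1e-9 on the count scale, absorbing the floating-point representation
  of rational thresholds; a support equal to the threshold is frequent.
* All p-values come from the exact hypergeometric tail
  (`stats::phyper`); an independent enumeration from binomial
  coefficients is used in the tests to confirm agreement to 1e-12.
* Equal-size ties in overlap filtering, equal-CS ties in alpha
  selection, and the canonical ordering of mined sets (decreasing
  support, then lexicographic) are all fixed deterministically.
* `set.seed`-style state is never mutated globally: seeded runs use a
  scoped RNG (`withr::with_seed`), so library calls do not perturb the
  caller's random stream.
* The empty gene set has no phenotype vector (an AND over zero rows is
  undefined) and is rejected; all-zero matrices yield an empty seed
  list, not an error.

## Problem sizes in the shipped checks

The test-suite benchmark uses the standard scenario (ten 10 x 5 blocks
in 100 x 50) with 10 replicates at noise levels {0, 0.05, 0.10} for both
block models, alpha selected on the 7-point grid and 500 randomizations
per bicluster — about half a minute of compute for the 60 runs. Miner
correctness is checked against the exhaustive oracle on 100 random
matrices up to 12 x 12 at six threshold combinations. These sizes were
chosen so the full suite documents the method's behavior at desk scale;
the algorithm itself has been shown to handle matrices of tens of
thousands of genes and thousands of samples in its original C++
implementation.

## Known limitations

* Binarization discards magnitude: a 4-fold and a 40-fold change are
  identical after thresholding. This is intentional — it is what makes
  the method robust across platforms — but it limits sensitivity to
  graded responses.
* Heavily overlapping implanted biclusters are reported with their
  shared region as a separate bicluster, which lowers recovery and
  consensus scores (visible in the overlap scenarios of the shipped
  benchmark).
* The extension step tests each gene marginally against a fixed
  phenotype vector; no multiple-testing correction is applied within a
  run, because the global alpha is itself tuned by the CS criterion.
* p-values of retained genes are exact but conditional on the seed's
  phenotype vector; they should be read as association strengths, not
  as calibrated significance statements about the final bicluster.
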