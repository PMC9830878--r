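---
title: "Methods: cross-species comparison of xylem single-cell lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species comparison of xylem single-cell lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical machinery: what
each method assumes, which knobs matter, how degenerate inputs are
handled, and where a genuinely open design choice was made.

## Quality filtering and normalization

Cells are retained when their total UMI count is **at least** the
threshold (default 500, the droplet convention; 100 is typical for
plate-based assays). The threshold is inclusive: a cell with exactly 500
UMIs passes. Normalization divides each cell by its total and multiplies
by a scale factor of 1000, so each non-empty cell row sums to exactly
1000; all-zero cells remain all-zero rather than becoming NaN. The log
transform is `log2(x + pseudocount)` with pseudocount 1, which maps zeros
to zero and preserves sparsity.

## The negative-binomial exact test

Differential expression between two cell groups follows the sSeq recipe
used by droplet-pipeline implementations:

* **Size factors** `s_i = total_i / median(total)`, computed over the
  cells of the two groups being compared. The median cell is the unit.
* **Dispersion** is method-of-moments per gene on size-factor-normalized
  counts, `phi_g = max(0, (var - mean) / mean^2)`, then shrunk toward the
  across-gene mean `xi` of the positive estimates:
  `phi~_g = delta * xi + (1 - delta) * phi_g`. The plug-in weight is the
  ratio of the between-gene variance of `phi_g` around its own mean
  (numerator, divided by G - 1) to its variance around the target
  (denominator, divided by G - 2), clamped to [0, 1]. When fewer than
  three genes are usable, or the denominator vanishes, `delta = 1`: full
  shrinkage to the common dispersion. On homogeneous data this weight
  approaches 1, which is the behaviour that makes the test stable with
  few cells; heterogeneous dispersions pull it below 1.
* **Exact p-value.** Conditional on a gene's pooled count t, each group
  sum is treated as NB with mean `S_k * mu` and dispersion `phi / S_k`
  (`S_k` = summed size factors; a sum of iid NB cells has this
  group-level dispersion to first order). The two-sided p sums the
  conditional probabilities of all splits no more likely than the
  observed one. A relative tolerance of 1e-8 on the log-probability
  treats floating-point-equal splits as ties; probabilities are combined
  with log-sum-exp. With dispersion 0 and equal size factors this reduces
  exactly to the conditional binomial test, which is how the
  implementation is validated against an enumeration oracle.
* **Large counts.** When both group sums exceed 900 (read as per-group
  *summed* counts — the natural reading for a switch meant to bound
  enumeration cost), the split fraction is approximated by a Beta
  distribution with `alpha_k = S_k * mu / (1 + phi * mu)`; the
  continuity-corrected tail beyond the Beta median is doubled and capped
  at 1. This generalizes the standard large-count beta approximation to
  unequal size-factor sums; with equal library sizes it coincides with
  the edgeR implementation, which serves as the cross-check in the test
  suite.
* Genes with zero counts in both groups are *skipped*: p = NaN, excluded
  from the number of BH tests.

DEG calls require BH-adjusted p < 0.05 and |log2FC| >= 1, where log2FC is
computed on size-factor-normalized group means with pseudocount 1 (the
pseudocount is configurable; 1 keeps the measure antisymmetric and finite
for zero-mean groups). Clusters with fewer than 5 cells are ineligible
and return empty calls rather than unstable ones.

## LCM anchoring

Per-cell Pearson correlations against each LCM cell type's mean TPM are
computed on the gene intersection of the two datasets, on the **linear**
scale (normalized UMI vs mean TPM). Whether to correlate in log space is
genuinely open; linear is the default because both abundance measures are
already relative, and a `log_space` switch is exposed. Cells with zero
variance over shared genes get NaN and are flagged, not dropped silently.
Cluster annotation averages cell correlations per cluster and takes the
argmax type; exact ties are broken by the declared type order and
flagged.

LCM up-genes for a focal type require mean TPM above 4 and log2FC >= 1
(pseudocount 1) against *every* other profiled type. When a bulk
differential analysis supplies adjusted p-values, an optional 0.05 filter
is applied on top; the package deliberately does not re-implement bulk
DE.

## Ortholog aggregation and cluster matching

Ortholog-group expression is the **sum** over all member gene copies (no
best-copy selection), aggregated before per-cell normalization, matching
the order of operations in the within-species pipeline. Cross-species
comparisons use the groups present in both species. Cluster mean profiles
are correlated all-against-all; clusters below 5 cells or explicitly
excluded are dropped and recorded. A pair is a mutual best hit when the
row and column argmaxes are reciprocal; ties are flagged and broken by
label order, so results are deterministic.

DEOs (differentially expressed ortholog groups) appearing in several
clusters are assigned to the cluster with the largest log2FC; without
fold-change information the assignment is flagged unresolved rather than
guessed.

## The distribution-overlap statistic

The MST is built on Euclidean distances (Prim's algorithm on the distance
matrix); determinism follows from the fixed input order, and duplicate
coordinates are legal (zero-weight edges). Removing the k cross-species
edges of a tree yields exactly k + 1 single-species subgraphs — an
identity asserted on every run. Each subgraph's center is the node with
minimal summed tree-path distance (closeness centrality with Euclidean
edge weights; hop counts would ignore geometry). A genuine tie is
possible — an edge splitting a component into equal halves makes its two
endpoints exactly tied — and is broken toward the lowest cell index, with
a flag.

Center densities use a product-Gaussian KDE with per-axis
normal-reference bandwidths `1.06 * min(sd, IQR/1.349) * m^(-1/5)`, where
m is the **number of centers** (the KDE sample size). When a species has
a single center or zero spread, the spread estimate is borrowed from all
of that species' cells while m stays the center count; this keeps the
single-center kernel wide rather than spuriously sharp. Because
bandwidths are per-axis, the statistic is exactly invariant to
translation and uniform rescaling but only approximately invariant to
rotation — the same property as any per-axis KDE.

The combined field `D = sum_S m_S (n_S/n) f_S` is evaluated directly at
cell coordinates (no grid interpolation; the exported grid exists for
plots). Values are divided by Z, the total of D over the reference
species' cells, then rescaled to [0, 1]:

* **self mode** divides by the pair's own maximum — appropriate for a
  single pair;
* **reference mode** divides by `(Z_ref, max_ref)` supplied from a
  designated reference pair and clamps to [0, 1] — this puts several
  pairs on one scale, and is the mode in which separated distributions
  correctly collapse toward 0% (a pair with two lone centers still has a
  well-shaped *relative* density surface, so self mode saturates; the
  information that interdigitation collapsed from ~n/2 centers to 1 lives
  in the m_S weights, which only a shared scale exposes). Proportions are
  proportions of *cells*, not grid area, which makes the disjoint limit
  behave as intended.

Bins: 500 equal-width bins on [0, 1]; the lowest bin is [0, 1/500). The
overlap O = 1 − p₁ is reported as a percentage.

## Kernel smoothers and lineage profiles

Local transcript abundance smooths normalized counts with a Gaussian
kernel on Euclidean distances in PC space (top-10 PCs by convention),
self-inclusive, so every smoothed value is a convex combination of
observed values. Relative abundance divides by the gene's mean local
abundance, making the per-gene mean exactly 1; gene-set scores average
relative abundances over the set. Neither smoothing bandwidth has a
canonical published value, so both defaults are declared choices recorded
in the output: the PC-space bandwidth is the median distance to the 30th
nearest neighbour (adapts to embedding density), and the Nadaraya-Watson
bandwidth on pseudotime is Silverman's rule of thumb. NW queries where
all kernel weights underflow fall back to the nearest observation with a
warning instead of returning NaN.

Moving-average profiles order cells by pseudotime (ties broken stably by
input order) and average windows of 21 cells slid one cell at a time,
giving n − 20 windows; per-feature maxima and means are emitted for
display rescaling.

## The synthetic generator

`simulate_two_species()` emulates the study design the pipeline targets:
two species sharing an eight-cluster branching lineage (ray organizer →
precursor → parenchyma; fusiform organizer → early → intermediate →
vessel element, with a libriform-fiber side fate), NB counts with
gene-wise dispersion in 0.05–0.3 and log-normal library sizes (median
~3000 UMIs), ortholog-group programs shared between species, 1–3 gene
copies per group per species with Dirichlet-split expression, planted
8-fold cluster markers (15 groups per cluster), smooth logistic ramps
along lineages for the remaining groups, a co-registered 2D embedding
built directly from branch curves (deliberately *not* via an embedding
algorithm, so overlap results do not depend on one), LCM-like TPM
profiles of the three terminal types with three replicates of 15%
log-normal noise, and full ground truth. Default sizes — 120 cells per
cluster, 600 ortholog groups — are large enough for stable DEG and
correlation behaviour while keeping the full test suite fast; they are
the package's chosen study conditions, not tuned quantities.

The divergence knob ε re-randomizes that fraction of the fusiform-branch
programs in species B and displaces its fusiform cells in the embedding
proportionally to ε and branch depth (up to 4 embedding units at the
terminal end), so increasing ε degrades both expression correspondence
and spatial overlap monotonically by construction.

RNG discipline: every component draws from a substream seed derived
deterministically from the master seed, so outputs are bit-for-bit
reproducible and adding one component does not perturb the others.

What the generator does **not** emulate: ambient RNA, doublets,
batch effects beyond library-size variation, UMAP/CCA integration
artifacts, and realistic gene-gene correlation structure. Tests passing
on this generator therefore validate the pipeline's statistical
machinery, not the biology of any particular dataset.

## Problem sizes and tolerances

The test suite validates exact identities (MST weight vs Kruskal,
closeness centers vs all-pairs brute force, BH vs the step-up definition,
Poisson-limit p-values vs binomial enumeration) at n ≤ 200 points, ≤ 50
node components, 100 random p-vectors and pooled counts ≤ 30, with
tolerances at or below 1e-9; stochastic properties (type-I rate in
[0.03, 0.07] under an NB null with 50 vs 50 cells and 2000 genes,
recovery of planted markers and cluster correspondences, monotone overlap
response over 10 seeds per condition) use fixed seeds and the sample
sizes stated in the acceptance script. These sizes are the package's
validation design.

## Known limitations

* The overlap statistic depends on the embedding given to it; it
  quantifies co-localization in that embedding, not in expression space.
* Reference-mode comparisons assume the compared embeddings share a
  coordinate scale (true when pairs come from one integration).
* The beta approximation is a large-count asymptotic; near the 900-count
  switch the exact and approximate p-values differ slightly, as with any
  such switch.
* The NB test assumes a common dispersion under the null for both
  groups; strong group-specific overdispersion is not modelled.
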