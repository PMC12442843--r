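---
title: "A hierarchical identity framework for developing cortical transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical identity framework for developing cortical transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortid)
```

## The problem

Neocortical cells organize into a nested taxonomy — broad **classes**
(glutamatergic neurons, GABAergic neurons, astrocytes, oligodendrocytes),
**subclasses** within them (e.g. intratelencephalic vs extratelencephalic
projection neurons), and fine-grained **types**. During development these
levels of identity are acquired in order: class-distinguishing
transcriptional programs mature first, then subclass, then type. Comparing
how far identity acquisition has progressed across experimental conditions
(in vivo, dissociated 2D culture, organotypic slice culture) requires a
fixed reference frame in which "has this cell acquired a type identity?"
has a quantitative, condition-independent answer.

`cortid` implements such a frame: a reference taxonomy is built once, each
population's *identity genes* are extracted per level, and query cells from
any condition are classified — independently at each level — by consensus
among their nearest reference neighbours, with an explicit **undefined**
outcome when the neighbourhood is mixed. Downstream summaries quantify
diversity (Shannon index of cluster composition), maturation (an
ordinal-regression pseudo-age), and which condition-dependent expression
changes are restored by a richer environment.

## Reference taxonomy

Counts are library-size normalized (`lognormalize()`: counts scaled to
10^4 per cell, `log1p`), z-scaled per gene with clipping at ±10
(`scale_expression()`), reduced by PCA (30 components), and connected into
a shared-nearest-neighbour graph (20 neighbours, Jaccard weights pruned at
1/15). Community detection (Leiden, modularity objective) at three
increasing resolutions yields the class, subclass and type partitions;
`assemble_tree()` links each child cluster to the parent-level cluster
holding the majority of its cells and records that majority fraction as the
link's *purity*, so non-nested partitions are made visible rather than
silently re-clustered.

Two scale notes. First, the z-score scaling is a deliberate, pluggable
stand-in for heavier variance-stabilizing transforms: the identity-score
contract below only needs per-gene comparability, and the z-scale keeps the
whole pipeline deterministic and dependency-light. Its metadata
(`$meta$center`, `$meta$scale`) can be reused to place a *query* dataset on
the *reference* scale, which is essential for identity scoring. Second,
resolution values are tied to the modularity formulation of the underlying
community-detection implementation; the conventional values 0.0005 / 0.001
/ 0.08 are kept as defaults for full-size datasets, but on the desk-scale
synthetic data used throughout the tests the same three levels emerge at
roughly 0.001 / 0.08 / 2, and tests therefore sweep a grid rather than
hard-coding one scale.

## Identity genes and identity scores

Markers are selected per level by a one-vs-rest comparison
(`find_level_markers()`): log2 fold change ≥ 0.6 on de-logged normalized
means (pseudocount 1), percent-expressing difference ≥ 0.1, and a
Bonferroni-adjusted Wilcoxon rank-sum p < 0.05. The fold-change and
percent screens are applied before testing (as the common implementations
do), while the Bonferroni denominator remains the full gene universe, so
the p-value adjustment does not depend on the screens.

The identity score of a cell for a population is simply the **mean scaled
expression of that population's identity genes** (`compute_identity_scores()`).
Per-level score matrices are concatenated into one identity-score space; a
2D UMAP of the reference scores is the *identity map* used for
visualization.

## Consensus classification and the undefined outcome

For each query cell and each level independently, the 10 nearest reference
cells are found by Euclidean distance; if 9 or 10 of them carry the same
label the cell is assigned that label, otherwise it is **undefined**
(`assign_identity()`; distance ties break by reference index, making the
rule exactly reproducible and testable against a brute-force oracle). A
cell can therefore be a confident glutamatergic neuron at class level while
remaining undefined at type level — exactly the signature of incomplete
identity acquisition.

`classify_cells()` exposes two classification spaces:

* `space = "embedding"` — neighbours in the 2D identity UMAP, with query
  cells placed by the out-of-sample transform of the reference-fitted
  embedding. This mirrors the visual map and is the default.
* `space = "score"` — neighbours directly in the concatenated
  identity-score space.

The choice matters for *degradation* analyses. An out-of-sample 2D
transform is attracted to the reference structure: a query whose type
scores are uniformly weak is still pulled inside whichever reference
cluster its residual noise favours, producing unanimous (and arbitrary)
neighbourhoods. In the full-dimensional score space the same cell sits
between type clusters and its neighbourhood is mixed, which is the
behaviour the undefined outcome is meant to capture. The package therefore
performs attenuation/degradation analyses in score space, and we recommend
the same for any analysis whose question is "how *well-defined* is this
identity", keeping the embedding for display and for routine assignment of
healthy data (where the two spaces agree).

## The synthetic data generator

`sim_config()` + `generate_reference()` draw negative-binomial counts for a
configurable nested taxonomy. Defaults define the desk-scale study
conditions used across the test suite: 2 classes / 4 subclasses / 8 types,
50 cells per type, 20 exclusive marker genes per population (every class,
subclass and type), 200 background genes, 10 `mt-` genes carrying ~1% of
each library, marker elevation 2^2, NB size 2 (dispersion 0.5), log-normal
library sizes around 800. The sparsity matters: with background means near
one count per cell, percent-expressing thresholds are informative, as in
real single-nucleus data.

* **Maturation** (`apply_maturation()`): each level's marker elevation is
  scaled by a ramp r(level, timepoint) ∈ [0, 1], with the class ramp
  saturating no later than subclass and subclass no later than type
  (defaults: class full by the second of four timepoints, subclass by the
  third, type by the fourth). The elevation interpolates —
  fold = 1 + (2^effect − 1)·r — so an immature program sits exactly at
  background, and the final timepoint reproduces the mature reference.
* **Condition effects** (`apply_condition()`): a condition is
  (α, ρ) — the designated type-marker programs of the affected
  (glutamatergic) class have their expected counts multiplied by α within
  their own population's cells, and a seeded fraction ρ of those genes is
  exempted ("restored", i.e. kept at reference means). Attenuation acts on
  expected counts directly (lost program expression shrinks the library
  rather than being redistributed), so the attenuated mean is exactly
  α × reference — an exact oracle for the restoration analysis. The
  restored-gene draw depends only on the configuration seed, so every
  dataset generated from one configuration shares the same truth.

What the generator does *not* emulate: ambient RNA, doublets, batch
effects, zero inflation beyond what low NB means produce, spatial
structure, or realistic gene-gene correlation. Passing tests on this data
demonstrate that the machinery is correct and that the inference logic
recovers planted structure at realistic sparsity; they do not certify
performance on any particular real dataset.

## Diversity

`shannon_index()` is the natural-log Shannon entropy of a cluster-count
vector, computed by the standard community-ecology routine; per-group
diversity (`diversity_by_group()`) counts a group's cells across clusters
of the *merged, unintegrated* datasets (`merged_cluster()`). Zero-count
clusters are excluded by the p > 0 convention. On desk-scale data the
merged graph resolves the planted types at resolution ≈ 3 on the
modularity scale (the default remains 1, the conventional setting for
full-size data).

## Pseudo-age

`train_ordinal()` fits the all-threshold hinge formulation of regularized
ordinal regression: minimize λ‖w‖² + Σ over cells and thresholds of
max(0, 1 − s·(w·x − θ_t)), where s = ±1 indicates whether the cell's
timepoint lies above threshold t. The objective is convex; we minimize it
by L-BFGS on a quadratically smoothed hinge (width 0.05, solver tolerance
~1e-9 relative) and sort θ afterwards (the all-threshold loss admits a
nondecreasing optimum). λ defaults to 1.

Cross-validation is stratified by timepoint; an in-sample cell's pseudo-age
is its out-of-fold score, while query cells get `predict_pseudoage()`
(w·x, renormalized by the fraction of model genes present). Model size is
selected by `select_gene_count()`: for each candidate count n, genes are
re-ranked by |w| *within each training fold* and the top n used — ranking
on the full data would leak the held-out cells into the gene choice and
make overlap decrease indefinitely with n. The quality measure is the mean
**overlap coefficient** (integral of the pointwise minimum of two kernel
density estimates; Gaussian kernel, Silverman bandwidth, 512-point grid
over the pooled range ± 3 bandwidths) between CV-score distributions of
consecutive timepoints — consecutive pairs are the discriminative ones for
ordering; all-pairs is available via `pairing = "all"`. The selected count
is the smallest candidate within 5% of the minimal overlap, honouring
"minimal number of genes with minimal overlap" without chasing noise.

## Restoration analysis

`find_degs()` applies the condition-contrast thresholds: |log2FC| > 0.6,
Bonferroni-adjusted p < 0.05, |Δ percent expressing| > 0.2. When condition
effects are population-specific, pooled class-wide comparisons dilute the
percent-expressing difference below threshold, so `restoration_analysis()`
accepts per-population group labels and unions per-type DEG lists; the
restored/in-vivo-only partition itself always uses class-wide condition
means: a DEG is **restored** when its organotypic mean is closer to the
in vivo mean than to the 2D mean (ties conservatively count as
in-vivo-only). The rule is invariant to constant shifts and is exposed for
replacement if a different restoration criterion is wanted.

## Numerical and design notes

* All randomness is seeded; stage seeds derive deterministically from one
  root seed (`pipeline_config()`), and UMAP runs single-threaded so results
  are bit-reproducible.
* Cluster ids are renumbered by decreasing size with ties broken by the
  smallest member cell id, making labels equivariant under cell
  permutations.
* k-NN consensus ties: distance ties break by reference index; a modal-label
  tie cannot reach the 9-of-10 consensus, so tie direction never changes a
  call.
* Empty cells: library-size normalization leaves all-zero cells at zero;
  their UMI/gene ratio is defined as 0 so they fail any minimum-ratio QC
  threshold.
* QC presets encode their sources' wording exactly, including strict vs
  inclusive boundaries ("more than 500 genes" strict; "1000 genes and
  more", "between 2500 and 15,000" inclusive). The inclusive reading of
  the UMI interval is a documented choice, not a printed fact.
* Problem sizes in the tests and acceptance script: 400–1,600 cells,
  ~500 genes, chosen as the smallest sizes at which every planted effect is
  recoverable at the configured power (e.g. 200 cells per compared group
  for DEG detection at the 0.2 percent-expressing threshold).

## Known limitations

* The marker-selection p-value adjustment (Bonferroni) and the pseudocount
  conventions follow the common single-cell tool family; other adjustments
  would change marker counts at the margin.
* The identity embedding cannot be serialized across sessions (it holds a
  live transform state); persist the identity-score matrices and labels
  instead and refit on load.
* Resolution values are implementation-scaled (see above); porting an
  analysis across community-detection backends requires re-sweeping.
* The restoration criterion is a nearest-mean rule on two contrasts; with
  strong compensation (organotypic overshoot) a correlation- or
  profile-based criterion may be preferable.

## A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(seed = 0)
ref <- generate_reference(cfg)
truth <- ref$truth

ln <- lognormalize(ref$counts)
markers <- do.call(rbind, lapply(c("class", "subclass", "type"), function(l)
  find_level_markers(ln, truth[[l]], level = l)))
gsets <- identity_gene_sets(markers)

query <- apply_condition(generate_reference(cfg), "2D")
res <- classify_cells(ref$counts, truth[, c("class", "subclass", "type")],
                      gsets, query$counts, space = "score", seed = 0)
population_proportions(res$assignment, grouping = query$truth$class)
```
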