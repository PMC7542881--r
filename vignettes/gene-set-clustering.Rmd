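---
title: "Clustering gene-set analysis results by shared gene content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering gene-set analysis results by shared gene content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsclust)
```

## The problem

Gene-set analysis returns lists of significant sets whose gene contents
overlap heavily: dozens of terms can describe one underlying signal, and
results from different tools (IPA, GREAT, plain GMT collections), different
annotations, or different species are not directly comparable. `gsclust`
reduces such results to a small number of clusters of gene-sets with similar
definitions. The method is deliberately annotation-agnostic: it uses only
the harmonized gene content, never term semantics, ontology structure or
protein-interaction networks, so it works identically for any tool or custom
database.

## Pipeline and model

1. **Load and merge.** Each input file becomes a collection of gene-sets
   with provenance (tool, experiment, species, optional category and
   p-value). Gene tokens are trimmed, uppercased and deduplicated at ingest;
   p-values are carried as metadata only and never filter anything. Merging
   concatenates collections; set identity is the provenance-qualified key
   `experiment::tool::name` (numeric suffixes on duplicates), so the same
   pathway found in two experiments stays distinct — required for
   cross-experiment comparison.
2. **Harmonize.** A user-supplied mapping table (source ID, namespace,
   species, target symbol) translates every token into one vocabulary.
   Tables are plain TSVs, so any orthology or ID resource can be used
   offline and deterministically.
3. **Similarity.** Every pair of sets is scored from its overlap counts
   (`C`, `P_i`, `P_j`, `N`). Default is the relative risk
   `RR = C*N/(P_i*P_j − C)`; Jaccard and Cohen's kappa are built in, and any
   function of the counts can be plugged in.
4. **Cluster.** K-means on the similarity-profile rows or average-linkage
   hierarchical clustering on a dissimilarity transform, with k chosen by
   silhouette, gap statistic or the elbow curve.
5. **Interpret and export.** Highlight scores, shared/unique genes per
   cluster, local hypergeometric ORA, heatmap/dendrogram/network renderings,
   and TSV/GMT exports.

### The gene universe N

The relative risk and kappa depend on the universe size `N`, described only
as the total number of genes in the experiments. Two readings are
defensible: the union of all loaded gene-sets, or the full measured
background of the experiment. The default is the union — it is always
available and makes results self-contained — while
`set_universe_override()` installs an explicit background when the user has
one. Jaccard is unaffected by this choice; RR and kappa scale with it, so
comparisons should fix one convention per analysis.

### Degenerate pairs

Two identical singleton sets give `P_i P_j − C = 0`; the metric returns an
infinity sentinel, and matrix construction replaces every infinite entry
with the largest *finite off-diagonal* value, recording the count in
`infinite_replaced`. Replacement rather than an error keeps real inputs
(which do contain one-gene sets) usable, and the count keeps it auditable.
The RR diagonal uses the same formula (`N/(P−1)` for sets above one gene):
self-similarity dominates each row without distorting the replacement
statistic, which deliberately ignores the diagonal.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `metric` | `"RR"` | RR is unbounded and spreads strong overlaps; Jaccard/kappa are bounded alternatives. |
| `universe_size` | union of sets | See above. Dimensionless count of genes. |
| `cap` | off (70 typical for RR) | Colour-scale clamp for heatmaps; optional clamp of clustering features. Capping before clustering is exposed but off by default, since clustering on raw profiles preserves the strongest signals. |
| `k` / `k_range` | user / `2..min(10, n−1)` | Cluster count; selection methods below. |
| `seed` | 1 | Drives k-means restarts and gap references; identical seeds give identical artifacts. |
| `linkage` | `"average"` | Average linkage is robust for similarity-derived dissimilarities; complete, single and Ward are available. |
| `unmapped_policy` | `"keep"` | Dropping unmapped tokens silently shrinks sets and biases overlap statistics; keeping them (uppercased) is conservative and the report makes the mapping rate visible. |
| `network_threshold` | — | Edges connect pairs with similarity strictly above the threshold (e.g. 15 on RR); strictly-greater is the documented rule. The threshold applies to the raw scores, before any cap. |
| `gap_B` | 50 | Gap-statistic reference datasets. |

## Numerical and algorithmic choices

* **K-means features.** Each gene-set is described by its row of the
  similarity matrix — its similarity profile to every set. Clustering these
  profiles groups sets whose relationships to the whole collection agree,
  which matches how the clustered heatmap of the matrix is read. Lloyd's
  algorithm with 25 restarts; empty-cluster draws are retried (up to 25
  restart rounds) before erroring.
* **Dissimilarity transforms** (hierarchical, silhouette): Jaccard `1 − s`;
  kappa `(1 − s)/2` (maps [−1,1] to [0,1]); RR and custom metrics
  `1 − s/max(s)` after infinity replacement. Each is monotone and bounded;
  no metricity is claimed and none is required by average linkage.
* **Label canonicalization.** Cluster labels are renumbered by decreasing
  size, ties by the smallest member set_id, so outputs are reproducible
  across platforms and label permutations can never leak into artifacts.
* **Elbow rule.** The criterion curve is total within-cluster sum of
  squares; the recommended k maximizes the discrete second difference (the
  sharpest bend). The full curve is returned so users can override.
* **Gap statistic.** `cluster::clusGap` with uniform references drawn over
  the original feature bounding box (`spaceH0 = "original"`), squared
  Euclidean dispersion (`d.power = 2`), and the standard-error rule:
  smallest k with `Gap(k) ≥ Gap(k+1) − SE(k+1)`.
* **Silhouette.** Mean silhouette width of the k-means labelling evaluated
  on the dissimilarity transform; recommended k is the argmax.
* **Highlight score.** No formula is standard for annotating clusters with
  a user gene subset; the package uses the per-set fraction
  `|genes ∩ subset| / |genes|` and the per-cluster mean — bounded in [0,1],
  insensitive to set size, trivially interpretable.
* **One-to-many mappings** expand to all target symbols (with a report
  count); many-to-one mappings collapse under set semantics. Expansion
  avoids an arbitrary winner; the report keeps it auditable.
* **ORA.** One-sided hypergeometric upper tail per (cluster, term) with
  Benjamini–Hochberg adjustment within each cluster, over the union of the
  data and annotation universes (a conservative universe; overridable).
  This is a deterministic, offline replacement for web-service enrichment
  plugins, which are out of scope.

## What the synthetic generator does and does not show

`planted_design()` builds `n_groups` disjoint pools of `pool_size` genes and
a shared background; each set draws `round(within_overlap · set_size)` genes
from its own pool and the rest from the background. Defaults — 3 groups × 8
sets, pools of 40, sets of 20 genes, 90% within-pool, background 200 — give
clearly separated groups whose only between-group overlap comes through the
background, i.e. a positive control in which the true partition is known.

Passing the planted-recovery tests shows the distance and clustering
machinery can recover structure when it exists. It does **not** show that
real GSA results contain such structure: real term-size distributions are
heavy-tailed, overlaps are hierarchical rather than block-like, and cluster
boundaries are genuinely fuzzy. The generator makes no attempt to mimic
GO/KEGG size distributions. Interpretation of real clusters still requires
the highlight scores, shared/unique gene lists and ORA outputs.

Test and acceptance runs use the default 24-set design, 20 seeded
replicates, k scanned over 2–6, and 50 gap references — sizes chosen so the
whole suite exercises every stochastic path in well under a minute per
property while keeping the recovery statistics stable across seeds.

## Command-line interface

`inst/cli/gsclust` is a thin Rscript over the package functions. `run`
executes the full pipeline from a YAML config; `load`, `distances`,
`optimal-k`, `cluster`, `network` and `ora` expose the individual stages,
chained through the package's file formats (GMT and TSV) since the
processing object itself is deliberately not persisted. Merging, plotting
and exporting are covered by `run` rather than separate subcommands: they
are only meaningful with the in-memory object present, and the library API
serves that use directly.

## Known limitations

* No semantic (ontology-graph) similarity and no network-weighted
  distances; overlap of harmonized gene content is the only signal.
* No GSEA-style ranked enrichment; the local ORA is over-representation
  only.
* Harmonization quality is bounded by the user's mapping table; no
  orthology inference is attempted.
* RR is unbounded and its scale depends on `N`; thresholds (network edges,
  caps) are analysis-specific constants, not universal defaults.
* Image outputs are renderings of tested structures (orders, edge lists,
  merge heights); their pixels are not part of the package's contract.
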