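---
title: "Module maps, median-threshold signatures and marker prevalence: methods"
author: "mesomap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module maps, median-threshold signatures and marker prevalence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesomap)
```

# The problem

Mesenchymal traits in carcinomas — stromal infiltration,
epithelial-to-mesenchymal transition, stem-like programs — leave coordinated
transcriptional footprints that single-gene tests miss. A standard way to
detect them across heterogeneous microarray (or RNA-seq) compendia is a
*module map*: a two-level gene-set enrichment analysis that first asks, for
every individual sample, which gene sets are over- or under-expressed, and
then asks whether the flagged samples concentrate within annotated sample
groups ("experiment sets" such as *MSCs*, *Breast Stroma* or *basal-like
tumors*). `mesomap` implements that stack end to end: compendium I/O and
normalization, signature derivation, the two-level hypergeometric module
map with FDR control, a dual marker-prevalence statistic, and hierarchical
clustering with the Eisen Cluster conventions, plus a seeded synthetic
compendium generator so every stage is testable without any download.

# The model

## Expression calls

Input compendia are gene-by-sample matrices on the linear intensity scale
or already log2-transformed. Before calling, values are log2-transformed
(if needed) and *gene mean centered*: from each data point the mean of its
gene across samples is subtracted, so every value is positive or negative
according to whether it lies above or below that gene's mean.

A gene is called **over-expressed** in a sample when its centered value is
at least `log2(c)` and **under-expressed** when it is at most `-log2(c)`,
where `c > 1` is a *fold-change* cut-off. The cut-off is interpreted as a
fold because it is set against the gene's mean on the intensity scale: a
cut-off of 1.5 flags genes at least 1.5-fold above (below) their mean, i.e.
±0.585 in log2 units. Typical values in practice range from 1.3 to 2.0
depending on the compendium; 1.5 is the default. Under- and over-calls use
the same magnitude of threshold (symmetric cut-off). Missing measurements
are never called and are excluded from the sample's testing universe.

## First level: gene sets in samples

For a sample with `N` measured genes, of which `K` belong to a gene set and
`n` were called in a direction with `k` of those inside the set, the
enrichment p value is the hypergeometric upper tail

$$P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

the probability that a random draw of `n` genes from the `N`-gene universe
would contain at least `k` set members. Tests with `n = 0` are retained
with `p = 1` so the result matrices stay rectangular. All sample-by-set
tests within one direction form a single family for Benjamini–Hochberg
adjustment, and a test is significant when its adjusted `q < alpha`
(default 0.05). The two directions are adjusted separately because they are
distinct (and mutually exclusive) hypotheses about the same sample.

## Second level: gene sets in experiment sets

The second level re-applies the same machinery one floor up: for a gene set
and direction, `N` is the number of samples tested, `K` the number flagged
significant at the first level, `n` the size of an experiment set and `k`
the number of flagged samples inside it; significance is again the
hypergeometric upper tail, BH-adjusted across all (set × group × direction)
tests pooled. A group can be *enriched* for the over-direction and another
group simultaneously *under-represented* via the under-direction — the
familiar red/green duality of module-map heat maps. Note this mirror is a
mathematical consequence of compendium-wide centering: a module genuinely
elevated in one group sits below its gene means in the complement, so
finding the complement under-represented is expected signal, not a false
positive.

The exact statistic GENOMICA-class tools use at this level is not published
alongside the method's description; the hypergeometric-on-flagged-samples
construction above is the established module-map reading and is documented
here as this package's definition. The FDR families (per direction at the
first level, pooled at the second) are likewise this package's choice; the
`fdr_method` slot accepts any `p.adjust` method.

## Median-threshold signatures

A signature is derived from one reference sample and a restricted universe
of genes (e.g. a dedicated stemness-, angiogenesis- or signal
transduction-related panel): the signature comprises the universe genes
whose expression in the reference sample is *higher than or equal to* the
intra-sample median of the measured universe genes. The median is taken
over the universe only — each signature is defined within its own
function-restricted panel, not against the whole genome. With `U` measured
genes and all values distinct the signature has exactly `ceiling(U/2)`
members; ties at the median are included, so the size can only grow.

## Dual marker prevalence

For a single marker gene (the motivating case is COX-2/PTGS2 as a
mesenchymal/stromal hallmark), two complementary percentages
cross-validate each other against normalization error:

* **intra**: the fraction of samples whose marker value strictly exceeds
  `k` times the *whole-genome intra-sample median* of that sample. Computed
  entirely within each sample, it is invariant to per-sample scale factors
  and asks whether the marker is highly expressed *within the sample's own
  transcriptome*.
* **cross**: the fraction of samples whose marker value strictly exceeds
  `k` times the *marker's median across all samples* of the dataset. It
  asks whether the marker is high relative to its typical cohort level and
  is deliberately sensitive to between-sample effects the first statistic
  ignores.

Both use strict `>` (the rule is "higher than `k` times"), default `k = 3`,
and operate on linear-scale values; log2 input is exponentiated first,
since "three times" is a fold statement and medians of centered data can be
zero or negative, which would make the rule meaningless. If a sample's
whole-genome median is 0, the sample counts as positive iff the marker
value is positive. In the per-group report both thresholds are recomputed
within each group, so groups are compared as self-contained datasets.

## Clustering

Profiles are optionally filtered by standard deviation (sample SD, `n - 1`
denominator; the `strict` flag selects between the `>=` and `>` reading of
a printed threshold) and clustered with **uncentered Pearson** similarity

$$s(x, y) = \frac{\sum_i x_i y_i}{\sqrt{\sum_i x_i^2 \sum_i y_i^2}}$$

and **average linkage** (UPGMA) on distances `d = 1 - s`, the Cluster 3.0
configuration. Missing values are handled pairwise-complete; a pair with no
overlap or a zero norm is an error, never a silent 0. Ties in the minimum
inter-cluster distance are broken toward the lowest pair of current cluster
indices, making dendrograms bit-reproducible. Merge heights under average
linkage are non-decreasing, so cutting into `m` clusters by removing the
`m - 1` highest merges is well defined. Dendrograms export to Newick (via
`ape`) and to Cluster 3.0 `.cdt`/`.gtr` tables.

# Normalization strategies

Three strategies cover the ways multi-study compendia are prepared:

| strategy | when | effect |
|---|---|---|
| `joint_center` | one study, or studies summarized together | concatenate, log2, center each gene across the whole compendium |
| `per_study_center` | independent studies of similar design | log2 and center each study separately, then concatenate |
| `none` | already-normalized input | concatenate only |

Per-study centering zeroes every gene's mean within every study, removing
additive (in log2) per-study batch offsets exactly; joint centering
provably cannot (the between-study per-gene mean gap survives untouched).
Probe-level summarization (e.g. RMA) is out of scope: the package consumes
already-summarized matrices and applies only the gene centering that
follows. The log2 transform takes an optional pseudocount (default 0) and
fails loudly on non-positive values rather than clamping, so mis-declared
scales surface immediately.

Whether centering should use all samples or only non-missing ones is not
fixed by convention; this package centers on the non-missing mean (and the
centered matrix satisfies "per-gene non-missing mean = 0" to 1e-9, tested).

# Tunable parameters

| parameter | units | default | why |
|---|---|---|---|
| `cutoff` (c) | fold | 1.5 | mid-range of the 1.3–2.0 span used on real compendia |
| `alpha` | — | 0.05 | conventional FDR significance level |
| `min_set_overlap` | genes | 3 | excludes degenerate 1–2 gene "sets" |
| prevalence `k` | fold | 3 | "three times the median" marker rule |
| SD filter `min_sd` | log2 SD | 0.4 | the moderate variation filter; use 1.5+ with `strict` for "most variable genes" |
| pseudocount | intensity | 0 | fail loudly rather than mask non-positive input |

# The synthetic generator

`synthetic_spec()` / `generate_compendium()` emulate the statistical
structure the analysis assumes: per-gene log2 baselines ~ Normal(7, 1)
(an RMA-like intensity distribution), additive per-study batch offsets,
Gaussian log2 noise (σ = 0.5), contiguous group blocks within each study,
gene-set modules planted at +δ (or −δ) log2 units in one target group, and
a marker gene multiplied by a fold factor in a stated fraction of its
target group. The marker's baseline is pinned at the population mean so
"fold over baseline" statements stay interpretable across seeds. The model
is log-normal on the linear scale so the log2 / centering / fold-cutoff
pipeline is exercised exactly as it is applied to real data.

Defaults describe the package's calibration conditions: 500 genes, two
30-sample studies with offsets 0 and +1 log2, groups tumor:stroma = 2:1
(a 20-sample stroma target), one 30-gene module at δ = 2 in stroma, five
size-matched decoy sets, and a PTGS2 marker at 10× in 40% of stroma
samples. One seed drives a fixed stream order (baselines → module gene
draws → decoy draws → marker-positive draws → noise), so outputs are
bit-reproducible and partial edits to the spec perturb as little as
possible.

What the generator does **not** emulate: probe-level artifacts
(cross-hybridization, spatial effects), heavy-tailed or sample-dependent
noise, correlated co-expression outside planted modules, missingness
mechanisms, and platform differences beyond an additive offset. Passing
tests therefore demonstrate algorithmic correctness and calibration under
a clean generative model — not robustness to every pathology of real
microarray cohorts.

```{r example}
sim <- generate_compendium(synthetic_spec(seed = 7))
norm <- normalize_compendium(sim$matrix, "per_study_center")
mm <- run_module_map(norm, sim$sets, sim$groups)
mm
subset(mm$second_level, significant)
prevalence_report_by_group(sim$matrix, sim$groups, "PTGS2", k = 3)
```

# Numerical and design choices

* **Fold reading of the cut-off.** Calls threshold at ±log2(c) on centered
  log2 values. Applying c directly in log2 units would turn "±1.3" into a
  2.46-fold rule, contradicting the fold-change meaning of the parameter.
* **Strict vs inclusive comparisons.** Signature rule: `>=` ("higher or
  equal to the median"). Prevalence: `>` ("higher than k times"). Call
  thresholds: inclusive at ±log2(c).
* **Hypergeometric tail.** `stats::phyper(k - 1, K, N - K, n, lower.tail =
  FALSE)`, floored at the smallest positive double; `k = 0` returns exactly
  1. Verified against exhaustive enumeration for all N ≤ 12 and a 1e5-draw
  permutation estimate for N ≤ 200.
* **Determinism.** No stage uses the RNG except the generator, which is
  seed-driven; UPGMA tie-breaks are fixed; pipeline TSVs print numerics at
  full (`%.17g`) precision, so a config + seed reproduces a byte-identical
  output manifest.
* **Degenerate inputs.** Empty sample universes, all-missing genes, zero
  norms, empty gene intersections, mixed scales, and non-numeric cells are
  hard errors naming the offender; undersized gene sets and empty groups are
  skipped with warnings.
* **Gene symbols** are upper-cased at ingest (the minimal mouse→human
  bridge, Ptgs2 → PTGS2); an optional user-supplied two-column mapping
  table is honored before case-folding for anything beyond case. Sample
  identifiers stay case-sensitive.
* **GCT v1.2** has no slot for a scale tag or study labels, so those
  round-trip through the TSV dialect's `#SCALE` / `#STUDY` header comments;
  writing a non-linear or study-labelled matrix to GCT warns and the reader
  takes an explicit `scale` argument.

# Problem sizes used in the test suite

The packaged checks run on deliberately modest sizes chosen as adequate for
their statistical purpose: exhaustive hypergeometric verification at N ≤ 12
plus 20 Monte-Carlo cases at N ≤ 200 (1e5 draws); 1,000 random p-vectors
(lengths 1–500) for the FDR equivalence; 20 null seeds (14,400 first-level
tests) for type-I calibration; 50 seeds per effect size δ ∈ {0.5, 1, 2}
for power; brute-force UPGMA agreement on instances of ≤ 8 items; and a
200-gene, 30-sample two-study fixture for the end-to-end golden-manifest
run.

# Known limitations

* The second-level statistic is a reconstruction (documented above), not a
  verified port of any specific tool's internals.
* Prevalence on log2-centered input is supported by exponentiating, but the
  resulting "fold over median" is a fold over the gene's mean-relative
  level, not over raw intensity; prefer linear or plain log2 input.
* Probe-to-gene collapsing is "first occurrence wins" at read time (with
  duplicate ids being errors); no summarization across probes is offered.
* Cluster labeling (e.g. assigning intrinsic-subtype names to dendrogram
  branches) is curator judgment and stays outside the package: only the
  dendrogram, cuts and marker summaries are produced.
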