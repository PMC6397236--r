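---
title: "lncnet: models, parameters and design choices"
author: "lncnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncnet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

`lncnet` screens disease-associated lncRNAs from gene-expression matrices
through a chain of classical systems-biology steps — moderated differential
expression, weighted co-expression modules, permutation module
preservation, a shortest-path-tree hub centrality, and over-representation
analysis. This vignette explains each model, its assumptions and tunable
parameters, the synthetic data the package validates itself on, and the
places where the design was genuinely open and a choice had to be made.

## The synthetic data model

Real studies of diabetic kidney tissue compare four groups — diabetic and
control glomeruli and tubuli (GD/GC/TD/TC). The generator
(`simulation_config()`, `generate_dataset()`) emulates that design on the
log2 scale, where microarray data live after normalization:

* The **disease indicator** (1 = diabetic) is standardized to `z`.
* Each planted module `m` has a latent **eigengene**
  `e_m = rho_m * z + sqrt(1 - rho_m^2) * eta`, `eta ~ N(0,1)` per sample,
  so `cor(e_m, z) = rho_m` in expectation — module–trait correlations are
  analytically controlled.
* A module gene with loading `lambda` is
  `x = baseline + lambda * e_m + sqrt(1 - lambda^2) * eps`,
  `eps ~ N(0, noise_sd^2)`; background genes have `lambda = 0`. With
  `noise_sd = 1` genes have unit variance and pairwise within-module
  correlation `lambda^2`.
* **DE genes** get an additive `sign * de_log2fc` in diseased samples, so
  `de_log2fc` is exactly the expected log2 fold change.
* **Batch offsets** are per-gene, per-batch `N(0, batch_sd^2)` shifts.
* **lncRNA labels** go to a random gene subset, with at least one per
  module when the budget allows; optional high-connectivity hub lncRNAs
  (`n_hub_lncrna`, loading `hub_loading = 0.95`) are planted in module 1
  and forced into the DE set — they are the known-positive targets of the
  end-to-end test.

All draws come from a single seeded stream in documented order (baselines,
lncRNA labels, DE selection, then eigengenes, batch offsets, noise), so a
fixed seed is bit-reproducible and `generate_paired_datasets()` can share
every planted assignment between a reference and a test dataset while
regenerating chosen modules as pure noise ("destroyed" modules).

The reference conditions are `standard_preset()`: 400 genes, five modules
of 60 genes with trait correlations (0.75, −0.75, 0.5, −0.5, 0), loading
0.8, residual sd 0.6 (a typical post-normalization residual spread), 15
samples per group, 40 DE genes at `de_log2fc = 2`, 30 lncRNAs with 2
planted hubs. Module-recovery and trait-recovery checks use the same
five-module structure with no DE planting, since DE shifts are a separate
axis of the design. Gaussian noise is an assumption, not a fact about
microarrays; heavy tails and probe-level artifacts are deliberately out of
scope, so passing tests demonstrate correctness of the machinery, not
robustness to every failure mode of real arrays.

What the generator does **not** emulate: raw probe intensities and
scanner artifacts, correlated (non-exchangeable) residuals, a realistic
spectrum of module memberships (all genes of a module share one loading),
and outlier samples other than by explicit construction.

## Reannotation and duplicate collapsing

Probe-to-gene reannotation is table-driven: the user supplies a
(probe, symbol, accession, biotype) table; probes missing from it are
dropped, and the per-platform lncRNA complement is wholly determined by
that table. Sequence-level re-mapping of probes against lncRNA reference
databases is an upstream task for which the table is the interface. When
several probes map to one symbol, the probe with the largest across-sample
variance wins — the most informative measurement of the gene — and exact
ties go to the lexicographically smallest probe id so results are
identical across platforms and runs. Loading policy for matrices: features
missing in more than 20% of samples are dropped, remaining gaps are filled
by the feature's median — a conservative standard for microarray matrices.

## Moderated differential expression

The two-group test uses an empirical-Bayes moderated t: per gene the
pooled variance `s^2` (with `d` residual df) is shrunk towards a prior
`s0^2` with `d0` prior df,

```
s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d),
t = log2fc / (s_tilde * sqrt(1/n_a + 1/n_b)),   df = d0 + d.
```

`(d0, s0^2)` are estimated by method of moments on `log s^2`: under the
scaled-F marginal, the excess of `var(log s^2)` over `trigamma(d/2)`
equals `trigamma(d0/2)`, inverted numerically; the mean equation then
yields `s0^2`. When the log-variances are no more dispersed than a
chi-square (excess ≤ 0) the prior df is infinite and `s0^2` is the plain
mean of the sample variances. The total df is capped at the pooled
residual df across genes. This estimator agrees with the widely used
reference implementation to ~1e-8 on shared inputs (checked in the test
suite). Genes constant in both groups are reported as degenerate with
`t = 0, p = 1` — even when the constant means differ, a deliberate
convention that keeps zero-variance artifacts out of the DEG lists.

DEG filtering is boundary-inclusive: `|log2fc| >= log2(2)` and
`p <= 0.05`, by default on **raw** p-values — the convention used when DEG
counts are produced upstream of BH-corrected enrichment — switchable to
adjusted p-values (`use_adjusted = TRUE`). Cross-tissue intersection takes
the DEGs present in both the tubuli and glomeruli contrasts, minus an
optional user-supplied exclusion list (the "irrelevant genes" of a given
study are study-specific, so the rule is an input, not a heuristic).

Batch removal is a per-batch location/scale adjustment: subtract the batch
mean, rescale to the pooled within-batch sd, restore the gene's global
mean. It makes no attempt to preserve condition contrasts through a model
matrix; with batches balanced over conditions (the study conditions here)
that bias is negligible, and the transform is exactly reproducible.

## The co-expression network

The network follows the weighted co-expression paradigm: Pearson
similarity `S`, **unsigned** soft adjacency `a = |S|^beta` (the unsigned
form treats strong negative co-expression as connection, which is what the
module–trait sign pattern of the synthetic data exercises), and unsigned
topological overlap

```
TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij).
```

`beta` (default: automatic) is chosen as the smallest power whose
connectivity distribution passes a scale-free fit at signed R² ≥ 0.8,
using the field's standard binned-frequency regression in which empty bins
are retained at near-zero frequency; without that convention the fit is
systematically underestimated on modular data. On independent noise no
power fits and the maximizer is returned with a warning — a diagnostic
that the data has no network structure.

Modules are clusters of the average-linkage dendrogram of `1 − TOM` under
a **static cut**; clusters smaller than `min_module_size` (default 30)
become grey. The default cut height is the midpoint of the largest gap in
the upper half of the sorted merge heights. The rationale: tight module
subtrees merge at clearly lower dissimilarity than the near-1 plateau
where unrelated genes join, and the widest gap separates the two regimes
adaptively and deterministically; a fixed quantile of merge heights (an
alternative we evaluated) frequently lands inside the plateau and merges
planted modules. `cut_height` stays exposed for users who prefer a fixed
value. Dynamic tree cutting and eigengene-based module merging are out of
scope. Colors follow the canonical module-color order (turquoise, blue,
brown, ...) by decreasing size, with size ties broken by smallest member
id, so labels are stable across runs.

Module eigengenes are first principal components of the z-scored module
expression (unit-norm sample scores), oriented so the mean correlation
with the module's genes is non-negative; a single-gene module's eigengene
is that gene's z-scored profile. Module–trait p-values use the exact
Student-t transform of the correlation, not the asymptotic z.

## Module preservation

`module_preservation()` asks whether a module found in the reference
dataset recurs in a test dataset, using two statistics on the
soft-threshold adjacency: mean within-module adjacency in the test network
(**density**) and the correlation of within-module connectivity kIM
between reference and test (**connectivity**). Each is standardized
against `n_permutations` (default 100) random gene sets of the same size
drawn from the full filtered universe — nothing is excluded, so null sets
may and do include module genes. `Zsummary` is the mean of the two Z
scores, read against the conventional thresholds: below 2, no evidence of
preservation; above 10, strong preservation. `medianRank` is the median of
the modules' per-statistic ranks (1 = most preserved) and is less
sensitive to module size.

A caveat the synthetic model makes visible: with exchangeable module genes
(one shared loading) the kIM pattern inside a module is pure sampling
noise, so the connectivity statistic is uninformative there and density
carries the signal; in universes dominated by a module/background split
the null kIM correlation is trivially high and Zconnectivity is biased
down. In the all-module filtered universe the pipeline actually analyzes,
Zsummary cleanly separates intact (>10) from destroyed (<2) modules and
grows monotonically with planted module strength. Real modules have
heterogeneous memberships, which restores meaning to the connectivity
component; only the two published component families (density,
connectivity) are implemented, not the full battery of preservation,
quality and accuracy statistics.

## Hub genes: the shortest-path-tree centrality

Within each disease-associated module, the continuous adjacency is
thresholded at `tau` (edge iff `a_ij >= tau`; default 0.02, which at
`beta = 6` corresponds to |r| ≈ 0.52) and genes are ranked by a
centrality built from shortest-path trees: for every root `s`, grow the
BFS tree `T_s`; `p_s(v) = 1` iff strictly more than `|V(T_s)|/4` of the
tree paths from `s` to the other vertices of `T_s` meet `v`; the score of
`v` is `sum_s p_s(v)`. Because the paths from `s` that meet `v` are
exactly those ending in `v`'s subtree, the count equals `v`'s subtree
size, which is how the implementation computes it; the test suite proves
equivalence against explicit path enumeration on thousands of random
graphs.

Three conventions had to be fixed where the statistic's definition leaves
room:

* **Meeting rule** — `v` counts when it lies on the path as an
  intermediate vertex *or as the destination itself* (`v != s` always).
  The emblematic star-center behavior (center scores `|V| − 1`, leaves 0)
  is identical under either endpoint convention; the choice is isolated
  in one place and documented.
* **Strictness** — "more than |V(T_s)|/4" is taken literally as a strict
  inequality.
* **Tie-breaks** — when shortest paths are non-unique the statistic
  depends on which tree is grown; the parent of a vertex is always the
  lexicographically smallest candidate at the previous depth, making the
  tree, and hence every score, deterministic. Scores are equivariant
  under order-preserving relabelings; an arbitrary relabeling can change
  tie resolution and therefore, legitimately, the scores.

Top-`k` selection (default `k = 20`) breaks score ties by higher weighted
degree in the continuous adjacency, then by id — on dense module graphs
where many scores are 0 this makes the ranking follow soft connectivity,
which is the intended notion of hubness. The CNC (coding/non-coding)
network connects hub genes at `|r| >= 0.7` and is exported as GraphML and
SIF with biotype, hub score and correlation attributes. The terminal *key
lncRNA* report intersects hub lncRNAs with the DEL list.

## Enrichment

Over-representation uses the upper-tail hypergeometric probability
`P(X >= k)` for overlap `k` of an `n`-gene list with a `K`-member term in
an `N`-gene universe, BH-corrected across the collection, significant at
`q <= 0.05`. The universe defaults to all genes surviving reannotation —
the expressed background, not the whole genome. A config switch
(`ease = TRUE`) reproduces the conservative EASE variant (overlap reduced
by one) used by DAVID-style tools; the plain tail is the default because
it is the exact test. Matching is case-insensitive by exact term id; no
ontology-graph propagation is attempted. Cross-species comparisons map
gene lists through a user-supplied ortholog table (one-to-many mappings
expand) and compare significant-term sets by Jaccard index (defined as 0
for an empty union).

## Pipeline, seeds and numerical conventions

`run_pipeline()` chains the stages (data, annotate, de, wgcna, preserve,
hubs, enrich) from one configuration; every stage writes TSV tables with
round-trip-safe `%.17g` formatting, and the run ends with a checksum
manifest and a JSON-lines log of parameters and events. One global seed is
expanded into per-stage substreams so changing one stage's parameters does
not perturb upstream randomness; the generator consumes its own seed. The
thresholds default to the printed conventions of this analysis style
(fold change 2, P 0.05, top-20 hubs, |r| 0.7 CNC edges, Z = 2/10), with
everything overridable per stage. Existing outputs are kept on re-runs
unless `force` is set; with a fixed seed, forced re-runs are
byte-identical.

Degenerate inputs are handled explicitly rather than silently: zero
variance in both groups flags the gene degenerate; a zero-variance trait
is an error; an all-equal connectivity vector skips that candidate power
with a warning; an empty module graph warns; a permutation null with zero
sd reports Z as missing.

Problem sizes used throughout the validation (chosen as the smallest at
which every planted effect is comfortably detectable): 300–1000 genes,
modules of 60, 60 samples in four groups, 100 permutations, 500 random
graphs per size for the centrality oracle, 10 replicates for calibration
figures.

## Known limitations

* The synthetic model is Gaussian and exchangeable within modules; it
  validates correctness, not robustness to real-array pathologies.
* Unsigned network only; signed adjacency and dynamic tree cutting are
  not implemented.
* The connectivity-preservation statistic is weak in mixed universes (see
  above); density dominates Zsummary in the synthetic setting.
* The hub centrality inherits the tie-break dependence of shortest-path
  trees; rankings are reproducible but not canonical on graphs with many
  symmetric shortest paths.
* Reannotation quality is entirely that of the supplied table; the
  package ships no reference annotation.
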