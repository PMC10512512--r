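---
title: "Transkingdom networks and BiBC: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transkingdom networks and BiBC: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tknet)
```

This vignette documents the statistical model behind `tknet`, the
parameters that matter and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the methodology left room.

## The analysis model

The pipeline targets four-arm studies: a control diet, a disease diet,
and two treatment arms layered on the disease background, with roughly
ten animals per arm. Measurements span kingdoms — tissue transcriptomes,
16S ASV abundances, bile-acid concentrations, and systemic metabolic
phenotypes — and the goal is to rank microbes by their inferred causal
leverage over the phenotypes.

### Normalization

Count data (genes, ASVs) go through counts-per-million, quantile
normalization, and `log2(x + 1)`; continuous data (bile acids,
phenotypes) are divided by their per-feature median across all samples.
Each omic and tissue is normalized independently; no cross-table
normalization is ever applied. Quantile normalization resolves ties by
averaging the reference values across the tied rank span (the limma
convention). With ties the per-column sorted multisets are then no longer
exactly identical — multiset equality and tie-averaging are mutually
exclusive contracts, and we follow the tie-averaging one; the equality
holds exactly on tie-free data and is tested there.

All downstream two-group tests are rank-based, so they are invariant to
the log2 step and to any monotone map applied uniformly across samples.
CPM is *not* a uniform map (it rescales each sample by its own library
size); the invariance tests are therefore stated for the steps after
per-sample scaling.

### Differential stage

Each feature is tested disease-vs-control and treatment-vs-disease with
two-tailed Mann-Whitney tests (exact for small tie-free samples, normal
approximation with tie correction otherwise). Fisher's combined
probability, `X2 = -2 * sum(log p)` against chi-squared with `2k` df, is
applied across cohorts; in a single-cohort design it degenerates to the
Mann-Whitney p itself, which is how the single-cohort default runs — the
statistic is computed, but it collapses by construction. FDR is
Benjamini-Hochberg within each (data type, tissue, comparison) stratum,
never across strata, so a tissue with many strong effects cannot lend
significance to another omic.

A feature enters the network when its disease comparison passes
`p < 0.05` and stratum FDR `<= 0.1` with a non-zero direction. "Improved
by a treatment" additionally requires the treatment comparison to pass
`p < 0.05` with a fold change *opposite* in sign to the disease effect;
direction is taken from the sign of the log2 fold change (group-mean
difference on the log scale), consistent with the network's
expected-sign rule. All printed thresholds are strict inequalities.

### Network stage

Spearman correlations are computed within each group separately, and
pooled by fixed-effect Fisher-z meta-analysis. Fixed rather than random
effects because the four groups are small, equal-design cohorts of one
experiment; with one group the statistic reduces to the classical
`atanh(rho) * sqrt(n - 3)` normal test. Per-group p-values use the t
approximation on the rank correlation (`t = r sqrt((n-2)/(1-r^2))`),
which handles ties without special cases and matches
`cor.test(..., exact = FALSE)` to near machine precision; for n = 10 the
difference from the exact permutation distribution is immaterial
relative to the downstream thresholds.

Edges survive only if

* every defined per-group p is at most 0.5 — a direction screen: at
  n = 10 it requires |rho| of roughly 0.24 in *every* group;
* the combined p is at most 0.05 (0.1 for the designated cross-omic pair
  classes: bile acids vs adipose genes, bile acids vs liver genes,
  ASVs vs ileum genes);
* the BH FDR within the edge's data-type pair class stays below a
  configurable ceiling (pipeline default 0.2, the top of the
  threshold-selection grid);
* all defined per-group correlations agree in sign. A meta-analyzed edge
  whose groups disagree in sign would be uninterpretable under the
  expected-sign rule below, so it is dropped before pooling can wash the
  disagreement out.

Edges among phenotypes are included (phenotypes are ordinary nodes).
"Unexpected" correlations — edges whose sign contradicts the product of
their endpoints' disease fold-change signs — violate the correlation
inequalities implied by a consistent disease response and are removed;
their pre-pruning share (PUC) is a quality statistic. Nodes with
direction 0 exempt their edges from pruning and are flagged.

Threshold selection, when requested, scans FDR in {0.01, 0.05, 0.1, 0.2}
by combined-p in {0.01, 0.05, 0.1} and picks the candidate whose
kept-edge negative:positive sign ratio is closest to that of the
noise-free complete graph (computed combinatorially from the disease
signs), breaking ties toward stringency. Within-omic pair classes are
filtered at half the candidate thresholds so they are never more lenient
than cross-omic classes; the exact stringency gap is not prescribed by
the methodology, so it is an exposed parameter with that default.

### BiBC and the random-network null

BiBC is purely topological: edge signs and correlation magnitudes are
ignored, pairs are unordered, and a node accrues the fraction of
shortest paths it lies on for every source-target pair it does not
belong to. Source and target nodes *can* accrue BiBC for other pairs —
that is precisely how a bottleneck microbe scores. The implementation
runs one BFS per group node (C++), accumulating
`sigma_s(v) * sigma_t(v) / sigma_s(t)` over pairs; it is validated
against brute-force enumeration of all shortest paths on hundreds of
random graphs. In addition to the raw pair sum, the report includes the
raw value divided by `|source| * |target|` (a single-network-stable
normalization) and the min-max scaled value.

The null ensemble draws G(n, m) graphs — uniform over edge sets of
exactly the observed edge count on the observed node set — keeping the
node-to-group assignment. The maximum node BiBC per draw is recorded;
nulls and the observed value are *jointly* min-max scaled (pooled
scaling; whether the original procedure scaled pooled values or divided
by the null maximum is not specified, and pooled scaling is the choice
that keeps the observed value inside [0, 1]). A one-sample Wilcoxon
signed-rank test compares the scaled nulls to the scaled observed value.
The test is exact (by convolution) for 25 or fewer non-zero differences
without ties, and otherwise uses the normal approximation with
continuity and tie corrections evaluated on the log scale:
`pnorm(log.p = TRUE)` keeps the magnitude of p-values that underflow
double precision (an ensemble of 10,000 nulls all below the observed
value yields log10 p of about -1630, reported as such; the linear-scale
p underflows to zero). The empirical exceedance fraction is reported
alongside.

When the causal question is which microbes act on phenotypes *through a
tissue*, the node universe is restricted before reconstruction (the
bundled pipeline keeps ASVs, adipose genes and phenotypes) rather than
restricting intermediaries afterwards; this matches the stated framing
of the reference analysis and keeps the null ensemble consistent with
the observed graph.

### Cell types and microbiota dependence

Cluster markers follow the cluster-vs-all-other-cells convention: mean
log-normalized expression, log2 fold change with an epsilon guard of
1e-9 on both means, and a Wilcoxon rank-sum p. Assignment is primary
rule first (log2FC > 0.25 and p < 0.05; among several qualifying
clusters the highest average expression wins), then a fallback to the
cluster with strictly maximal average expression; exact ties leave the
gene unassigned, and the applied rule is recorded per gene. The fallback
can be required to also pass the fold-change rule via a switch, off by
default. Single-cell QC is order-sensitive and fixed: cells below 2500
UMIs, then cells above 0.5 mitochondrial ratio, then genes detected in
fewer than three *remaining* cells.

Microbiota dependence crosses the treatment-vs-disease fold change with
the SPF-vs-germ-free fold change: genes significant on both axes with
opposite signs are `dependent_reversed` (the treatment undoes what the
microbiota imposes). The significance gate on the microbiota axis
(Mann-Whitney p < 0.05 of the GF/SPF comparison) is a package choice —
the original gate is not printed — and a sign-only mode is provided as
the alternative reading.

## The synthetic study generator

`simulate_study()` emulates the data shapes of the motivating design:
four groups of 10 samples; 200 adipose, 40 liver and 40 ileum genes; 50
ASVs; 27 bile acids; 10 phenotypes. Counts are negative binomial
(dispersion 0.02) around log-normal latent means; bile acids and
phenotypes are log-normal. It plants, with full ground-truth bookkeeping:

* **Disease effects**: 40% of features per data type shifted by
  ±2 log2 units in the disease group, with directions balanced half up,
  half down within each data type — on the relative-abundance scale a
  one-sided shift would mostly be absorbed by the library
  renormalization, which is a property of CPM, not of the biology being
  emulated. The causal ASV blooms at 1.5 times the standard effect,
  as the strongly diet-responsive bottleneck taxa it emulates do.
* **Treatment reversals**: of the affected features, 50% revert to the
  control mean under treatment b, 10% under both treatments, 5% under
  treatment a — mirroring a study in which the second treatment is the
  effective one.
* **A causal chain**: one mid-abundance ASV loads on two per-sample
  latent factors at full strength, `(u + v)/sqrt(2)`; the other affected
  ASVs load on the community factor v, and 12 chain genes plus *all*
  affected phenotypes load on the chain factor u (phenotypes are
  systemic endpoints downstream of the microbe, not an independent
  module). The causal ASV is thereby the only articulation point between
  the microbial community and the host side, i.e. the planted
  topological bottleneck. Loadings are calibrated so that the pairwise
  latent-scale correlation within a module equals
  `module_cor_strength` (0.9) and the causal node's own coupling
  `causal_coupling` (0.97): with loading `b` and residual log-scale
  noise `sd`, `r = b^2 / (b^2 + sd^2)`, so `b = sd * sqrt(r / (1 - r))`.
  The orthogonal-factor design is deliberate: any Gaussian construction
  in which community and chain correlate through a *shared* factor
  produces transitive community-phenotype correlations of the order of
  the product of the direct ones, which would thread detectable direct
  edges past the bottleneck and destroy the very topology the method is
  supposed to detect. Conversely, orthogonality caps the causal node's
  own edge correlations at `1/sqrt(2)` times the module strength; the
  four-group direction screen therefore removes a slice of its edges in
  every run, which is why the chain carries redundant members on both
  sides.
* **Exact in-sample orthogonality**: the three factors are centered,
  orthogonalized (QR) and variance-normalized *within every group*. With
  10 samples per group the realized correlation of independently drawn
  factors fluctuates with a standard deviation near 1/3; left
  uncorrected, such fluctuations occasionally manufacture consistent
  transitive community-host correlations that pass every edge filter and
  crown a spurious bottleneck. Orthogonalizing the synthetic design
  matrix removes that artifact without changing the marginal model.
* **Abundance geometry**: baseline log2 abundances are wide
  (genes 3-12, ASVs 3-11) and the chain members sit mid-range so their
  planted shifts stay interior to the quantile grid. Both are
  load-bearing: quantile normalization maps each sample onto a common
  grid, so a shifted feature stranded at the extreme ranks has no rank
  crossings left and its effect (and correlations) would be erased —
  an artifact of normalization geometry the generator must respect, not
  a statistical tuning.

`simulate_gf_spf()` produces the paired germ-free/SPF table in which
chain members shift in SPF opposite to their treatment-b effect (the
microbiota pushes what the treatment reverses), and
`simulate_marker_table()` plants the chain genes as myeloid cluster
markers passing the primary rule with maximal average expression there.

What the generator does **not** emulate: phylogenetic correlation among
ASVs, zero-inflation and sequencing-depth artifacts of real 16S data,
batch effects, gene-gene regulatory structure beyond the single host
module, nonlinear phenotype responses, and read-level noise. Passing the
recovery tests therefore demonstrates that the pipeline's inference is
correct *for data satisfying its own assumptions*; it does not certify
performance on real data with structure the generator omits.

## Validation and problem sizes

The test suite validates each stage against independent oracles
(brute-force shortest-path enumeration for BiBC; closed-form chi-squared
and hypergeometric tails; `metafor`'s fixed-effect estimator; `limma`'s
quantile normalization; hand-enumerated rank distributions) and then the
whole chain against planted truth. The end-to-end study-scale checks
use: 20 pipeline runs at the default configuration with 1,000-network
nulls (the planted ASV ranked first in 19 of 20 during calibration, with
null p below 1e-3 in each; a 100-seed pre-freeze pilot gave 99/100
without the edge-FDR ceiling); 100 zero-effect simulations for the
type-I rate of the Mann-Whitney screen (pooled positive rate 0.047 at
alpha 0.05); and 200 random graphs for BiBC oracle equivalence. A run
whose source and target layers end up disconnected has every BiBC equal
to zero; such a run is counted as a recovery failure, never as a rank-1
tie. The planted-edge retention of the default filters at study
conditions is about 78% (per-seed 73-85% in the pilot) — the four-group
direction screen is the binding constraint — and the corresponding test
asserts the pilot-fixed bound of 50%.

## Numerical choices and degenerate inputs

* `atanh(rho)` at |rho| = 1 is clamped to |rho| = 1 - 1e-6.
* Fisher's method clamps p = 0 to the smallest positive double, with a
  warning.
* A group in which a feature is constant contributes `NA` to that
  feature's correlations; the pair retains its remaining groups.
* All-tied Mann-Whitney input returns p = 1.
* Zero-median rows are left unscaled by median normalization and
  reported.
* Min-max scaling of a constant pooled set (observed equal to every
  null) is degenerate; the significance routine returns p = 1 with a
  warning.
* Duplicate edges are collapsed at network assembly; self-edges are
  dropped; isolated eligible features are reported but not drawn.
* Random-null reproducibility is seed-exact; the pipeline derives its
  stage seeds from the single configuration seed.
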