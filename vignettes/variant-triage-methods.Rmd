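---
title: "Variant triage, allele aggregation and interaction clustering: methods"
author: "VariantTriage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant triage, allele aggregation and interaction clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantTriage)
```

# Scope and data model

`VariantTriage` analyses *annotated* candidate-gene variant tables from
small exome cohorts: one row per (patient, variant) observation carrying the
gene symbol, dbSNP identifier (or the novelty marker `"New"`), HGVS changes,
consequence class, in-silico predictor profile, a reference population
allele frequency with its scope, zygosity, chromosome class, inheritance
mode, gene-panel category and clinical classification. Alignment, variant
calling and annotation are upstream and out of scope; so are live queries to
annotation services — every external quantity arrives as an input column or
file.

The central containers are S4 classes with validity methods:
`VariantTable` (the observations), `Cohort` (patients and sexes, from which
the allele denominators derive), `GenePanel`, `InteractionGraph` (a wrapped
undirected `igraph` with edge confidences in [0, 1]), and the result classes
`AggregationResult`, `ClusterPartition`, `EnrichmentResult`.

Two dialect quirks of published tables are part of the file contract: a
trailing asterisk on a frequency cell marks a *global* rather than
Latino-stratum frequency, and numbers may be written in spreadsheet
scientific notation (`3.95 x 10^-4`). The statistics use the frequency as
given regardless of scope — published tables mix scopes without
re-normalising — but the scope is carried into every report.

## Deliberately preserved annotation inconsistencies

The packaged case-study tables reproduce their printed source faithfully,
including its internal inconsistencies, which the package surfaces rather
than corrects:

* a known rsID with an absent ("NF") reference frequency (MNS1 c.605delA) —
  carried as frequency-absent and listed by `annotationNotes()`; the strict
  rule that only *novel* variants lack a frequency is therefore enforced in
  one direction only;
* a hemizygous call recorded for a female proband (OFD1 c.2610G>C in
  T181001) — kept as printed and reported once a cohort with sexes is
  available;
* the same variant printed with two different frequencies in two panels
  (DNAI1 c.203G>A: 2.89×10⁻⁵ vs 2.89×10⁻⁴) — cohort aggregation emits a
  flagged not-computable row naming both values instead of picking one.

# Triage rules

Missense deleteriousness is a consensus over three predictors, counted as
*abnormality sets*:

* **SIFT** — abnormal iff the label is `D`; when only a score is present,
  abnormal iff score < 0.05. The printed label wins over the numeric
  threshold when both exist: published tables contain calls such as
  `D (0.085)`, and trusting the label reproduces them.
* **PolyPhen2** — HumDiv and HumVar jointly count as *one* predictor,
  abnormal iff either label is `PD` or `D`. Counting the sub-models
  separately would make almost every variant reach "two abnormalities" and
  would contradict the novel-variant rule's published examples.
* **MutationAssessor** — abnormal iff the impact label is `M` or `H`.

A missense variant is deleterious with ≥ 2 abnormalities, or ≥ 1 when novel
(`dbsnp == "New"`). The novel-variant relaxation applies to missense rows
only; whether it should extend to loss-of-function classes is unstated in
the source material, so the conservative reading is implemented.
Loss-of-function and splice classes use CADD PHRED ≥ 20 (inclusive), the
conventional top-1%-damaging threshold; when CADD is absent a LoF-Tool `PD`
label substitutes (no numeric LoF-Tool cutoff is published, so the label is
trusted and the score merely stored). When CADD is present it decides alone.
These rules are monotone: adding an abnormal predictor can never revoke a
deleterious call (a property the test suite checks over all 8 × 2
abnormality/novelty combinations).

Panel filtering keeps every non-synonymous observation in the
previously-associated (TGA) panel regardless of clinical class, but only
VUS/likely-pathogenic/pathogenic observations in the cilia panels.
"Possibly pathogenic" in source vocabularies is mapped to the standard
*likely pathogenic* tier.

Compound heterozygosity is ≥ 2 distinct (by cDNA change) deleterious
heterozygous variants of one gene in one patient. Allele counting assigns
dose 1 to heterozygotes and hemizygotes, 2 to homozygotes; identical
cross-panel repeats of an observation collapse, while the same patient
reported with two different zygosities for one variant is an error.

# Aggregation statistics

For an observed allele count *k* out of *n* cohort alleles at reference
frequency *p*, the package reports both the binomial point probability
P(X = k) and the upper tail P(X ≥ k), evaluated in log space via
`lchoose`. The point probability is the headline number by default because
it is the convention in this candidate-gene literature (the packaged case
study's printed 0.2184 for 2/22 alleles at p = 0.053 is the point mass; the
tail at the same parameters is ≈ 0.327). The point mass is **not** a
calibrated p-value — it is labelled "point probability" in every report —
whereas the upper tail is super-uniform under the null, which the test
suite verifies over 200 seeded null cohorts.

The X-chromosome denominator is 2·females + males. The source material
never states its X denominator (all its printed n = 22 statistics are
autosomal), so this choice only affects new analyses.

The sex-contingency test is the two-sided Fisher exact test under the
probability-ordering convention (sum of hypergeometric probabilities of all
margin-fixed tables no more probable than the observed one, relative
tolerance 1e-7). It is implemented directly over `dhyper` and cross-checked
in the tests against both `stats::fisher.test` and a factorial-based full
enumeration. A published sex-difference p-value for OFD1 (0.520) depends on
sex-stratified reference counts that are not available offline, so the
operation is generic and that value is not a package target; the same holds
for a published 6.02 × 10⁻³ for PIBF1, which is not reproducible from the
printed carrier configurations under either the point or tail statistic at
either plausible denominator, and is deliberately not implemented.

# Network methods

**Markov Clustering.** Edge confidences (used directly as transition
weights) plus unit self-loops are column-normalised into a stochastic
matrix; iteration alternates expansion (matrix square, by default) and
inflation (elementwise power 2.0, column re-normalisation) until the
largest entry change falls below 1e-6 or 100 iterations. Clusters are the
weakly connected components of the non-zero structure of the limit matrix
(entries above 1e-8), relabelled contiguously (1-based, by first node
appearance) for determinism. Expansion preserves block structure, so
disjoint graph components are never merged; raising inflation does not
coarsen partitions on the synthetic suite (checked empirically — MCL offers
no strict theorem here). Because cluster granularity depends on the unknown
inflation used by external database front-ends, cluster *counts* from such
services are not comparable and are not targets.

**Enrichment.** Database-proprietary analytic enrichment p-values are
replaced by a documented, seedable permutation test: the whole graph is
randomised by degree-preserving double-edge swaps (10 attempted swaps per
edge per permutation, via `igraph::rewire(keeping_degseq())`), the
within-set edge count is recounted, and
p = (1 + #{null ≥ observed}) / (1 + B). The add-one convention bounds p
below by 1/(B + 1) and keeps the test valid at finite B; degree sequences
are asserted to be exactly preserved in the tests, and the null p-values
are verified super-uniform over 200 seeded unstructured graphs.

# Synthetic data: what it emulates, what it does not

The generator mirrors the case-study's structure — 11 patients, 9 male /
2 female by default, so the denominators 22 and 13 arise naturally:

* **Genotypes** are Hardy–Weinberg draws: Binomial(2, AF) per autosomal
  patient; on the X, Binomial(2, AF) for females and Bernoulli(AF) for
  males, recorded as hemizygous.
* **Predictor profiles** are drawn conditional on a ground-truth label:
  deleterious missense truth gives SIFT ~ U(0, 0.05) labelled `D`,
  PolyPhen2 ~ U(0.9, 1) labelled `PD`, MutationAssessor `M`/`H`; benign
  truth gives SIFT ~ U(0.2, 1) `T`, PolyPhen2 ~ U(0, 0.3) `B`,
  MutationAssessor `N`/`L`; LoF classes draw CADD ~ U(25, 45) vs U(5, 15).
  A discordance rate (default 0.1) flips one predictor to the opposite
  condition to exercise the 2-of-3 logic; a single flip cannot defeat the
  consensus, so classification accuracy against truth stays ≥ 0.9.
* **Graphs** are planted-partition (stochastic block model) draws with edge
  confidences U(0.4, 0.95) and returned truth labels.

A single root seed derives per-stream sub-seeds (genotypes per variant,
predictors per variant, graph) so stages regenerate independently;
identical seeds give byte-identical files.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: linkage disequilibrium between variants,
correlated predictor errors (real predictors disagree systematically, not
independently), frequency misspecification between the reference population
and the cohort's ancestry, relatedness, and the literature-driven topology
of real interaction databases. The packaged interaction edge list is
likewise a labelled *synthetic* stand-in encoding the case-study's asserted
pairwise interactions plus background edges, not a database export; results
on it demonstrate mechanics, not biology.

# Numerical and design choices

* Binomial terms are computed in log space; degenerate p ∈ {0, 1} is
  handled exactly. The pmf is cross-checked against `dbinom` and against an
  arrangement-enumeration oracle (n ≤ 10) at 1e-12.
* Fisher's probability-ordering comparison uses relative tolerance 1e-7,
  matching the common exact-test convention for ties.
* MCL tie-breaks are deterministic by construction (component readout +
  first-appearance relabelling); non-convergence at the iteration cap
  returns a partition flagged `converged = FALSE` rather than an error.
* Problem sizes in the test suite are chosen for tightness at desk scale:
  3 × 10-node planted blocks for recovery (adjusted Rand index ≥ 0.9),
  200 null cohorts / 200 null graphs with 100 permutations each for
  calibration, margin totals ≤ 40 for the Fisher enumeration oracle.
* Reports print probabilities to 6 significant digits; every numeric
  comparison in the tests uses tolerances, never string equality. Each
  pipeline run writes a manifest (config, input MD5 checksums, seed,
  package and R versions) sufficient to reproduce its outputs.

# Known limitations

Beyond the synthetic-data caveats above: the triage rules inherit the
published label-over-score convention, so tables annotated with scores only
will behave slightly differently around the SIFT threshold; the point
probability is reported because it is the field's convention, not because
it is the better-calibrated statistic (prefer `mode = "upper_tail"` for
inference); and the enrichment test conditions on the degree sequence only —
it does not model edge confidences under the null.
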