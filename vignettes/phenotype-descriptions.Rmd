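---
title: "Phenotype descriptions for chromosome deletions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype descriptions for chromosome deletions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvphen)
```

## The problem

Most chromosome deletions are unique in position, size and gene content, so a
newly diagnosed patient rarely has a textbook phenotype to consult. The
approach implemented here predicts the phenotype of an index deletion from
the observed phenotypes of cohort patients whose deletions are *functionally*
similar: the clinical consequence of a deletion is assumed to be driven
largely by the haploinsufficient (HI) genes it removes, and most strongly by
a small curated set of dominating-effect (DE) genes whose loss produces a
prominent, highly penetrant phenotype of its own.

The pipeline has four stages, each a module of this package:

1. **Gene classification** — call each gene HI or not from three published
   predictors.
2. **Pairwise similarity** — score patient pairs on deletion size, location,
   gene and HI-gene overlap, plus DE-gene concordance.
3. **Grouping** — collect the patients genotypically similar to the index at
   the highest usable HI-gene similarity threshold (the tier algorithm).
4. **Description** — report the features prevalent in that group, and
   evaluate descriptions by their positive predictive value (PPV).

## Gene classification

Three scores predict a haploinsufficiency effect: the HI percentile (low is
pathogenic), pLI and pHaplo (high is pathogenic). A score satisfies its
criterion when `hi_percent` is in `[0, 10]`, `pli >= 0.9`, or
`phaplo >= 0.86`. A gene is an HI gene when it satisfies at least two of
three criteria with all scores known, or at least one of two with one score
missing. Two readings were left open by that rule and resolved here:

* **Boundary inclusivity.** "Between 0% and 10%" is read inclusively at both
  ends; a percentile of exactly 0 or exactly 10 satisfies the criterion.
* **A single known score.** The two stated cases follow a majority-of-known
  pattern (3 known need 2, 2 known need 1), which extends naturally to
  1 known needing 1. That extension is the default; setting
  `hi_criteria(single_score_classifies = FALSE)` makes a lone score never
  sufficient, for users who prefer the conservative reading.

A gene intersects an aberration when they share at least one base pair
(1-based closed coordinates throughout, so `[100, 200]` and `[201, 300]` do
not overlap). Whether a gene only partially covered by a deletion should
count as deleted is genuinely ambiguous at breakpoint resolution; the
any-overlap rule is the simplest defensible choice and is applied uniformly.

## Pairwise genotypic similarity

For two patients with aberrations of the same type on the same chromosome,
all same-type aberrations are first merged per patient and compared as one
unit (a ring chromosome with two deletions is compared on its total content).
Four measures are computed:

* `hi_gene_similarity` — Jaccard index of the two HI-gene sets;
* `gene_jaccard` — Jaccard index of the full gene sets;
* `location_jaccard` — base-pair Jaccard: overlapping bases divided by the
  bases covered by the union of both merged interval sets;
* `size_jaccard` — the smaller total affected length over the larger, a
  location-free size ratio.

plus the binary `de_concordant`: whether the affected DE-gene sets are
*identical*. DE concordance is a hard gate — a patient with a different DE
set is never grouped with the index, whatever its other similarity.

Design choices worth knowing:

* **Symmetric vs asymmetric HI similarity.** The HI-gene overlap can be read
  either as a symmetric Jaccard index or as the fraction of the *index's* HI
  genes that the other patient shares. The symmetric Jaccard is the default;
  `similarity_settings(hi_similarity_mode = "index_fraction")` switches to
  the asymmetric reading. The two agree whenever the deletions have equal
  HI-gene counts.
* **Empty sets.** Two deletions that both remove zero HI genes are
  indistinguishable with respect to HI-gene content, so both-empty sets score
  Jaccard 1 (one empty against non-empty scores 0). The same convention
  applies to the base-pair Jaccard (vacuously, since aberrations are
  non-empty) and to DE concordance (both-empty is concordant).
* **Threshold comparisons** use `>=` with an absolute tolerance of `1e-9`, so
  a 7/10 overlap passes a 0.7 threshold despite binary floating point.
* **Size and location filters are disabled by default.** The default
  chromosome-6 profile gates only on DE concordance and HI-gene similarity;
  the size/location/gene filters exist for users who want them
  (`min_size_jaccard` etc.). Their exact definitions (above) are isolated in
  the similarity module so they can be swapped without touching grouping or
  evaluation.

## The tier algorithm

Ideally descriptions would use only patients with 100% HI-gene overlap, but
such groups are usually too small. The tier algorithm trades similarity for
group size in fixed steps, walking a descending 0.1-step threshold grid:

| HI-gene similarity | minimum group size |
|---|---|
| 1.0, 0.9, 0.8 | 20 |
| 0.7, 0.6 | 15 |
| below 0.6 | DE fallback: only if the index deletion contains a DE gene, at the highest threshold yielding >= 15 |

The first (highest) threshold whose group meets its size rule wins. Group
size counts connections only — the index is never a member of its own group.
The DE fallback is uncapped: if 0.0 is the first threshold reaching 15
members, it is used, on the expectation that a shared DE gene dominates the
phenotype regardless of residual HI-gene overlap. Patients without a DE gene
whose groups stay below the size rules receive no description at all rather
than a low-confidence one.

## Descriptions and their evaluation

A feature enters the description when it is present in at least 20% of the
connected group (`prevalence_min`) **and** in at least 2 members
(`min_carrier_count`), so that at the minimum evaluable group size of 5 no
feature ever rests on a single patient. The 20% rule uses a ceiling — in a
group of 17 a feature needs 4 carriers — computed as
`ceiling(0.2 * N - 1e-9)`: the small slack stops binary floating point from
bumping exact multiples (0.2 × 15 evaluates slightly above 3, and a naive
ceiling would demand 4 carriers where the rule says 3). Features are sorted
by descending prevalence with ties broken by term id, making the output
independent of member ordering.

An `unknown` status counts as *not present* by default, in numerator and
denominator alike. This mirrors how unreported features in literature case
reports are handled: authors describe what is remarkable, so absence of
mention is treated as absence, at the cost of underestimating prevalence.
`unknown_mode = "drop"` provides per-feature denominators over members with
a known status instead, but is off by default because it inflates prevalence
estimates from exactly those patients with the least complete data.

PPV of a description is the fraction of its features actually present in the
index. The evaluation harness (`leave_one_out_sweep()`) uses each patient as
an index once, at every threshold of the grid, keeping only indexes with at
least 5 connections (`min_connections_for_ppv`) — eligibility is recomputed
at every threshold, so the per-threshold eligible counts shrink as the
threshold rises. PPV is computed on a user-supplied feature subset
(typically curated main features, preventing a main feature and its
sub-features from being double counted). Medians summarise the skewed PPV
distributions; strata (DE vs non-DE indexes, group-size bands) are compared
with two-sided rank-sum tests, normal approximation with tie and continuity
correction — appropriate at the stratum sizes in use, and degenerate strata
(empty, or constant pooled values) report `NA` rather than a fabricated
p-value.

## The synthetic-cohort generator

No public patient-level dataset accompanies this class of analysis, so the
package ships a generator (`simulate_cohort()`) producing cohorts with the
statistical structure the method assumes, used both in the test suite and as
the demonstration dataset. It emulates:

* **Clustered deletions** — deletion centres fall in a few hotspot regions
  with configurable weights (default three hotspots totalling 0.75), so
  genotypically similar groups exist; sizes are log-normal.
* **Gene-driven penetrant features** — every HI gene carries fixed feature
  links (3 per DE gene, 1 per other HI gene by default); deleting the gene
  makes each linked feature present with the configured penetrance (0.9 for
  DE genes, 0.4 otherwise). Background features occur at a genotype-
  independent 3% rate.
* **Literature under-reporting** — literature-cohort patients have each truly
  present feature masked to `unknown` with probability 0.68, reproducing the
  asymmetry in reported feature counts between parent-reported and
  literature patients (roughly a third of features retained).

Default scale: 452 patients (literature fraction 310/452) on a 171 Mb
chromosome with 600 genes of which 20% are HI (about 120) and 5 are DE, and
log-normal deletion sizes with median 4.5 Mb — giving a median of about 3 HI
genes per deletion, the density a real single-chromosome deletion cohort
shows. Scores are drawn all-pathogenic for HI-destined genes and all-benign
otherwise, so the 20% score-missingness never flips a verdict and the
configured HI fraction is exact; this sacrifices realism of borderline score
combinations for a controllable ground truth.

What the generator does **not** emulate — and what passing tests therefore do
not show about real data: realistic gene density variation and gene-family
clustering; features shared across neighbouring genes or acting through
position effects; incomplete penetrance varying per feature; correlated
feature co-occurrence (syndromic patterns); measurement noise in breakpoint
calls. Results on synthetic cohorts validate the *machinery* (grouping,
inclusion rules, PPV accounting), not clinical performance.

All randomness flows from a single integer seed (`simulation_config(seed=)`);
the gene map and the patient sampler use `seed` and `seed + 1` so each is
individually reproducible, and the global RNG state is restored afterwards.

## Numerical and degenerate-input choices

* Merging intervals collapses adjacent blocks (`[1,100] + [101,200]` becomes
  `[1,200]`); total length and gene content are unchanged by this.
* `ppv()` raises an error on an empty description rather than returning 0 or
  `NA` silently; sweep records with an empty description carry `ppv = NA`
  and are excluded from medians while still counting toward group sizes.
* `select_tier()` returns an explicit `"none"` group rather than erroring,
  since "no description" is a legitimate clinical outcome.
* Inputs on any genome build other than hg19 are refused at read time;
  coordinate conversion is deliberately out of scope (do it upstream).
* Duplicate patient ids, duplicate (patient, term) phenotype rows and
  malformed intervals are hard errors; a DE flag on a gene failing the HI
  rule is a warning, since the DE list is curated independently of the
  scores.

## Problem sizes used by the tests and the acceptance script

The test suite exercises cohorts of 10-40 patients for exact
oracle-equivalence checks (brute-force per-base and set enumeration), 250
patients for the DE-vs-non-DE PPV contrast, and 25 identical-deletion
patients for the end-to-end recovery check (tier 1.0, PPV 1). The
acceptance script runs the generator at its full default scale (452
patients) and sweeps the complete threshold grid; both finish in well under
a minute on a single core. These sizes are the package's own choices,
balancing resolution of the medians against quick iteration.

## Known limitations

* Groups are index-centric stars, not cliques: members are similar to the
  index, not necessarily to each other.
* Terms are opaque codes; no ontology reasoning is performed, so a feature
  and its ancestor term are unrelated unless the user's feature subset
  encodes that structure.
* The size- and location-Jaccard definitions are reasonable but not uniquely
  determined by the published description; they are confined to the
  similarity module so alternatives can be swapped in.
* Duplications are supported by the machinery (`type = "duplication"`) but
  all defaults were chosen for deletion cohorts.
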