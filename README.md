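# cnvphen

Tailored phenotype descriptions for chromosome deletions, predicted from the
observed phenotypes of genotypically similar patients.

## The problem

Structural chromosome aberrations are mostly unique in position, size and
gene content, so for a newly diagnosed deletion there is rarely a cohort of
"the same" patients to learn the expected phenotype from. `cnvphen`
implements a genotype-first matching strategy for cohorts of patients with
coded phenotypes (HPO or custom terms, `present`/`absent`/`unknown`): it
finds the cohort patients whose deletions are *functionally* similar to an
index deletion and summarises their phenotypes into a clinical description
for the index. It is aimed at clinical-genomics researchers curating
chromosome-disorder cohorts and at tool builders who need the grouping,
description and evaluation machinery behind such predictions.

## The model

**HI genes.** A gene is haploinsufficient (HI) when, of its three scores —
HI percentile, pLI, pHaplo — it satisfies at least two of the criteria
`hi_percent ∈ [0, 10]`, `pLI ≥ 0.9`, `pHaplo ≥ 0.86` when all three are
known, or at least one of two when one score is missing.

**Similarity.** For two patients with same-type aberrations on the same
chromosome (merged per patient), genotypic similarity is measured by Jaccard
indices of size, location, gene and HI-gene content:

```
J(A, B) = |A ∩ B| / |A ∪ B|
```

with sets of genes for the gene measures and base pairs for the location
measure, plus a hard gate: the affected dominating-effect (DE) gene sets —
curated HI genes with prominent, highly penetrant phenotypes — must be
identical.

**Grouping (tier algorithm).** Walking a descending HI-gene similarity grid
(1.0, 0.9, …, 0.0), the index's connected group is accepted at the highest
threshold meeting that tier's size rule: ≥ 20 members at thresholds ≥ 0.8,
≥ 15 at 0.7/0.6, and below that only when the index deletion contains a DE
gene (at the highest threshold still yielding ≥ 15).

**Description and PPV.** A feature enters the description when present in
≥ 20% of the group (ceiling) and ≥ 2 members. Descriptions are scored by
positive predictive value,

```
PPV = (description features present in the index) / (description features)
```

and `leave_one_out_sweep()` recomputes PPV for every patient (used as index
once, requiring ≥ 5 connections) at every threshold — the machinery used to
calibrate the tier rules.

Because no public patient-level cohort exists, the package includes a
synthetic-cohort generator (`simulate_cohort()`) with clustered deletion
hotspots, gene-driven penetrant features and literature-style
under-reporting, used by the test suite and the examples below.

## Worked example

```r
library(cnvphen)

sim <- simulate_cohort(simulation_config(seed = 42))
sim$cohort
#> <cnv_cohort> 452 patients (142 parent, 310 literature), 452 aberrations, 170 phenotype terms

ann   <- annotate_cohort(sim$cohort, sim$genes, chromosome = "6")
group <- select_tier(ann, "P0065")
group
#> <connected_group> index P0065: 16 members at HI-gene similarity >= 0.6 [hi>=0.6,n>=15]

desc <- generate_description(group, sim$cohort$phenotypes, sim$feature_universe)
desc
#> <phenotype_description> index P0065, group of 16 [hi>=0.6,n>=15]: 7 feature(s)
#>   CUST:0111            7/16  0.44  CUST:0111
#>   CUST:0113            6/16  0.38  CUST:0113
#>   CUST:0115            6/16  0.38  CUST:0115
#>   CUST:0110            5/16  0.31  CUST:0110
#>   CUST:0106            4/16  0.25  CUST:0106
#>   CUST:0109            4/16  0.25  CUST:0109
#>   CUST:0112            4/16  0.25  CUST:0112

idx_present <- subset(sim$cohort$phenotypes,
                      patient_id == "P0065" & status == "present")$term_id
ppv(desc$features$term_id, idx_present)
#> [1] 0.2857143
```

Reading this: no threshold ≥ 0.8 gave patient P0065 a group of 20, but at
HI-gene similarity ≥ 0.6 there are 16 patients sharing its dominating-effect
content, so the 0.6 tier applies. Seven features are present in at least 20%
of those 16 members (and in at least 2 of them) — e.g. `CUST:0111` in 7/16
(prevalence 0.44). Two of the seven are present in the index itself, giving
this description a PPV of 0.29.

The evaluation harness sweeps all patients and thresholds:

```r
rec <- leave_one_out_sweep(sim$cohort, sim$genes, sim$feature_universe, "6")
summarize_sweep(rec)   # per-threshold group-size counts, median PPV,
                       # DE / group-size stratifications with rank-sum tests
```

A thin command-line interface wraps the same functions
(`inst/cli/cnvphen.R`, subcommands `classify-genes`, `describe`, `evaluate`,
`simulate`); the default chromosome-6 settings profile ships at
`inst/extdata/chr6-profile.yaml`.

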