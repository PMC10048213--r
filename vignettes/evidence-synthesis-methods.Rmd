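---
title: "Methods: synthesizing GWAS evidence for diabetic retinopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthesizing GWAS evidence for diabetic retinopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drmeta)
```

## The problem

Genome-wide association studies (GWASs) of diabetic retinopathy (DR) and its
subphenotypes — proliferative / sight-threatening DR and diabetic macular
edema or maculopathy — have reported many significant signals with strikingly
little agreement between cohorts. Before any one signal is taken seriously it
should be (i) tiered by the strength of its discovery evidence, (ii) checked
for convergence with other independent GWASs, and (iii) pooled across
independent replication studies with a random-effects meta-analysis guarded by
heterogeneity, quality and publication-bias diagnostics. `drmeta` implements
that protocol as a reusable, offline-testable pipeline, together with a
seeded generator of synthetic case-control cohorts so the whole analysis can
be exercised and validated without any external data.

## Signal curation and tiering

Reported signals enter as a TSV mapped through a column dialect (a shipped
dialect understands GWAS-Catalog association exports). Every row is validated
— positive p-value, integer coordinate, bracketed confidence interval when an
odds ratio is present — and failing rows go to a rejects report rather than
being dropped, so accepted plus rejected always accounts for the input.
Chromosome labels are normalized (`chr10` → `10`) with the original retained
for round-tripping.

Two significance tiers are applied with strict `<` comparisons:
*suggestive* at `5e-5` and *genome-wide* at `1e-7`. The genome-wide default
is deliberately the stricter-than-conventional `1e-7` used in the DR GWAS
literature this pipeline targets; both thresholds are plain configuration
values, so the conventional `5e-8` is one argument away. Boundary equality is
excluded at both tiers: a p-value of exactly `1e-7` does not pass.

Studies whose controls were general-population (not diabetic-without-DR)
samples are kept in the catalog but excluded from overlap and pooling by
default — their control arms answer a different question — and the exclusion
can be overridden per run.

## Cross-study overlap

Within each phenotype group (never across groups, which are analyzed
separately) the pipeline looks for convergent evidence two ways:

1. **Identical signals** — the same rsID (case- and whitespace-insensitive)
   reported by two or more *distinct* studies. Repeats within one study are
   not independent evidence and never form a cluster.
2. **Proximal signals** — a graph is built linking pairs of signals from
   different studies on the same chromosome with `|pos1 − pos2| ≤ 100,000`
   (inclusive, 1-based coordinates; the half-width is configurable), and
   connected components with at least two distinct studies are reported.

Components may chain: two signals more than one window apart can co-cluster
through an intermediate signal. We chose component semantics as the default
because the goal is locus-level grouping, and we report each cluster's span
so chained extents are visible; a pairwise mode is available for users who
want strictly windowed pairs. Coordinates are assumed to be on a single
declared genome build per catalog file — no liftover is attempted.

Clusters export as a TSV report and as 0-based half-open BED intervals.
An empty result is recorded explicitly ("no overlap") per phenotype group,
because absence of convergence is itself a finding worth a row.

## Allelic effects per replication study

Replication evidence arrives either as genotype counts or as a reported
odds ratio with a 95% CI.

**From counts.** Under the allelic model each subject contributes two
alleles, so genotype triples `(n_EE, n_EO, n_OO)` collapse to
`a = 2n_EE + n_EO` effect and `b = 2n_OO + n_EO` other alleles per arm, giving
a 2×2 table with `OR = ad/bc`, `β = ln OR` and
`SE = sqrt(1/a + 1/b + 1/c + 1/d)`. If any cell is zero the
Haldane–Anscombe continuity correction adds 0.5 to all four cells (flagged on
the estimate); tables without zeros are never altered, and a strict policy
that errors instead is available.

**From a reported CI.** `SE = (β − ln lower)/1.96` with `β = ln OR`, using
the lower limit only. When an upper limit is supplied it is used purely as a
consistency check: a warning fires if the interval is asymmetric on the log
scale by more than 0.05, which usually signals a transcription error in the
source table.

One record per study per SNP is enforced. When both counts and a reported
(covariate-adjusted) estimate exist for the same study, the adjusted one is
preferred; counts-based and adjusted estimates of one cohort must never both
enter a pool. Studies declared to share a cohort group are de-duplicated,
keeping the largest and most recent record.

**Quality gating.** Each counts-based estimate carries the control-arm
Hardy–Weinberg deviation p-value (1-df χ² goodness of fit by default; an
exact enumeration test is available for small samples, and monomorphic
controls return p = 1 with a flag). Estimates are flagged — never deleted —
when Newcastle–Ottawa stars are ≤ 6 (inclusive) or HWE p < 0.05 (strict);
flagged studies are candidates for omission in the sensitivity analysis. The
χ² flavor and α = 0.05 are our choices and both are configurable. Note that
the conservative exact test and the χ² test can return visibly different
mid-range p-values (the exact test orders outcomes by probability, χ² by
distance from expectation); they agree closely in the deviation tail where
the gate actually operates.

## Random-effects pooling

Pooling uses the DerSimonian–Laird moment estimator, the random-effects
default of the mainstream systematic-review software this protocol mirrors.
With fixed-effect weights `w_i = 1/SE_i²`:

* `β_F = Σw_iβ_i / Σw_i`, `Q = Σw_i(β_i − β_F)²`
* `τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))`
* random weights `w*_i = 1/(SE_i² + τ²)` give `β_R`, `SE_R`,
  `OR = exp(β_R)` with `exp(β_R ± 1.96·SE_R)` as the 95% CI
* `I² = max(0, (Q − (k−1))/Q)·100`, defined 0 when `Q = 0`;
  `I² < 50%` (strict) is classed low heterogeneity
* two-sided normal p on `z = β_R/SE_R`; summary significance at p < 0.05,
  strict, uncorrected across SNPs (the report footer says so)

The CI uses the plain normal 1.96 quantile — no t or Hartung–Knapp
adjustment, and REML is out of scope — to match the reference software's
convention. When `τ²` truncates to zero the random-effects numbers equal the
fixed-effect numbers exactly (same arithmetic path, not just numerically
close), which the tests assert bitwise.

**Sensitivity.** Leave-one-out re-pools with each study omitted (or, in
restricted mode, only quality-flagged studies) and records whether the
p < 0.05 verdict flips. A pool of two studies yields no sensitivity results
— omission would leave a single study — and warns instead.

**Publication bias.** A funnel table (per-study `β` vs `SE` plus pseudo-95%
guide lines around the pooled effect) is emitted for visual inspection only;
no Egger/Begg asymmetry statistic is computed, deliberately, because the
protocol this mirrors assesses funnels visually and an automated statistic
at k ≤ 5 is noise.

## LD proxies and annotation

Index SNPs gain proxies from a local PLINK-style LD table at
`D′ ≥ 0.8 AND r² ≥ 0.8` — conjunctive and inclusive, exactly as the
thresholds are usually printed. The LD population is an opaque label on the
file. Functional annotations (SIFT, PolyPhen, CADD, RegulomeDB rank, eQTL
gene and p) are joined from a local TSV; the join is total — every queried
rsID yields a row, unannotated ones flagged — and no scores are ever
computed, only read. A small annotation fixture for rs4462262, rs7903146 and
rs7074440 ships with the package for tests and examples. The shipped signal
catalog uses real published rsIDs and p-values but synthetic placeholder
coordinates where the sources print none (the file name says so); only
p-values feed the tiering logic.

## The synthetic-data generator

The generator emulates the replication cohorts the meta-analysis consumes:

* control genotypes are multinomial draws from Hardy–Weinberg proportions at
  the control effect-allele frequency (default 0.3, a common-variant
  frequency typical of the replicated DR loci);
* each study draws `ln OR_i ~ N(ln OR_true, τ²)`;
* the case allele frequency uses the exact allelic-OR inversion
  `p_case = OR·p / (1 + p(OR − 1))` — not a logistic approximation — so the
  simulated allelic odds ratio is exactly the estimand the analysis targets;
* case genotypes are Hardy–Weinberg draws at `p_case`;
* per-cohort sample sizes jitter uniformly by ±20% (switchable) around the
  spec sizes; defaults of 1000/arm and k = 5 reflect the modest replication
  cohorts in this literature;
* the HWE-violation mode distorts control genotype probabilities with a
  fixed inbreeding-style coefficient (default F = 0.15, large enough to be
  reliably detected at realistic control-arm sizes);
* every generator takes a mandatory seed and is bit-reproducible under it.

For overlap testing, `simulate_catalog()` places background signals on a
coarse grid whose spacing exceeds twice the window, so accidental clusters
are impossible by construction and the planted clusters are exactly the
ground truth; planted proximal pairs sit at exactly the window half-width,
exercising the inclusive boundary.

What the generator does *not* emulate — and therefore what passing tests do
not demonstrate about real data: linkage disequilibrium between simulated
variants (cohorts are a single variant each), covariate adjustment,
population stratification, genotyping error, and ascertainment quirks of
real replication studies. It validates the estimator and the pipeline
plumbing, not the epidemiology.

## Validation and problem sizes

The test suite checks, among other things: the formula implementations
against hand-worked 2×2 tables; the pooled estimator against an
independently coded brute-force reference (to 1e-8 over 100 random
configurations, k ∈ 2..10) and against `metafor::rma(method = "DL")`; the
overlap search against a quadratic pairwise oracle on 1000-signal random
catalogs; and parameter recovery — with true OR 1.4, τ = 0, k = 50 and
2000 per arm over 500 seeded replicates, the pooled log-OR bias stays below
0.02 and the 95% CI covers the truth in 92–98% of replicates. Those sizes
(500 × 50 cohorts of 4000 subjects) keep the full recovery study in the
tens of seconds while leaving Monte-Carlo noise well below the tolerances.

## Degenerate inputs and numerical choices

* `k = 1` pools are refused; `k = 2` pools run but yield no sensitivity.
* `Q = 0` defines `I² = 0` (avoiding 0/0); `τ²` truncates at zero.
* Monomorphic control arms: HWE p = 1 by convention, flagged.
* A degenerate reported CI (`lower = OR`) is an error, since SE must be
  positive.
* Zero-total arms are rejected at construction.
* Cluster output is sorted by chromosome and span start, so results are
  invariant to input row order.

## Limitations

The pipeline pools whatever per-study estimates it is given; it cannot
reconstruct the published pooled DR odds ratios unless the user supplies the
underlying per-study replication data, which live in the original
replication publications rather than in any shipped fixture. rsID merge
history is not resolved (identical means string-equal), coordinates are
taken on faith from the declared build, and no multiple-testing correction
is applied across SNPs — all faithful to the protocol being implemented, and
all worth revisiting if this grows beyond it.
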