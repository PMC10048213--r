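# drmeta

Evidence synthesis for diabetic-retinopathy GWAS signals.

GWASs of diabetic retinopathy (DR), proliferative/sight-threatening DR and
diabetic macular edema have reported over a hundred signals with little
agreement between cohorts. `drmeta` is an R package for the protocol a
systematic reviewer applies to that literature:

1. **Curate & tier** — read a GWAS-catalog-style signal table (with a
   column-mapping dialect), validate every row into signals or a rejects
   report, and tier p-values at *suggestive* (p < 5×10⁻⁵) and *genome-wide*
   (p < 1×10⁻⁷, strict) significance per phenotype group.
2. **Overlap** — within each phenotype group, find signals shared between
   independent studies: identical rsIDs, then connected components of
   cross-study pairs within a ±100 kb window (inclusive), exported as TSV
   and BED.
3. **Effects** — one log odds ratio and standard error per replication
   study, from genotype counts under the allelic model
   (OR = ad/bc, SE = √(1/a + 1/b + 1/c + 1/d), Haldane–Anscombe 0.5
   correction only when a cell is zero) or from a reported OR with 95% CI
   (SE = (ln OR − ln lower)/1.96), with Hardy–Weinberg and
   Newcastle–Ottawa quality flags.
4. **Meta-analysis** — DerSimonian–Laird random effects:
   τ² = max(0, (Q − (k−1))/(Σw − Σw²/Σw)), weights 1/(SEᵢ² + τ²), 95% CI
   via the normal 1.96 quantile, Cochran's Q, I² (< 50% = low
   heterogeneity), leave-one-out sensitivity with significance-flip
   detection, and funnel-plot tables for visual bias assessment.
5. **Annotate** — LD proxies at D′ ≥ 0.8 AND r² ≥ 0.8 from a local
   PLINK-style table, joined with local SIFT/PolyPhen/CADD/RegulomeDB/eQTL
   annotations.

A seeded synthetic-data module generates case-control cohorts with a
specified true allelic OR, control allele frequency, per-arm sizes and
between-study heterogeneity τ, plus signal catalogs with planted overlap
clusters, so the entire pipeline runs and is validated offline.

## Worked example

Simulate four replication cohorts at a true allelic OR of 1.38 (control
effect-allele frequency 0.3, 1200 per arm), derive per-study effects, and
pool them:

```r
library(drmeta)

cohorts <- simulate_meta(sim_spec(true_or = 1.38, control_maf = 0.3,
                                  n_case = 1200, n_control = 1200,
                                  k_studies = 4, tau = 0, seed = 2026))
est <- do.call(rbind, lapply(cohorts, function(g) {
  e <- or_from_table(alleles_from_genotypes(g))
  e$hwe_p <- as.numeric(hwe_test(g$control_counts))
  e
}))
res <- dersimonian_laird(quality_gate(est))
res
#> random-effects meta-analysis (DerSimonian-Laird), k = 4
#>   OR = 1.39 [1.31, 1.48], z = 10.63, p = 2.17e-26
#>   Q = 1.571, tau2 = 0.0000, I2 = 0.0% (low heterogeneity)
```

The pooled OR of 1.39 [1.31, 1.48] recovers the simulated 1.38; Q below its
3 degrees of freedom truncates τ² to zero, so I² = 0 and the random-effects
result coincides with the fixed-effect one. Leave-one-out confirms no single
cohort drives the verdict:

```r
for (s in leave_one_out(quality_gate(est))) print(s)
#> omit sim_study_1: OR = 1.41, p = 9.61e-22
#> omit sim_study_2: OR = 1.37, p = 1.26e-18
#> omit sim_study_3: OR = 1.38, p = 8.39e-20
#> omit sim_study_4: OR = 1.40, p = 1.01e-20
```

The same analysis runs file-to-file through `run_pipeline()` (or the thin
wrapper `inst/scripts/run_pipeline.R`) from a YAML/JSON config naming the
catalog, optional replication and annotation inputs, the thresholds and a
seed; it writes catalog, tier, overlap, meta, sensitivity, funnel and
annotation reports plus a machine-readable manifest of every threshold used.
Example inputs ship under `inst/extdata/` (the signal catalog there carries
real published rsIDs and p-values with synthetic placeholder coordinates, as
its filename notes).

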