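# mmaomics

Analysis toolkit for multi-layered omics studies of methylmalonic
aciduria (MMA) and similar inborn errors of metabolism. It is written
for analysts who have patient-derived tables — phenotype records,
paired RNA/protein expression matrices, annotated variant tables,
isotopologue peak areas, AP-MS identification and quantification
tables — and need the bespoke statistics that tie them together into a
severity-stratified, mechanism-oriented workup. Because real cohorts of
this kind are access-restricted, the package also ships a seeded
synthetic cohort generator with the same statistical structure, so the
entire pipeline is testable and demonstrable without any download.

## What it computes

* **Phenomics** — a 0–5 clinical severity score (CSS) from five binary
  indicators; a mixed-type Spearman correlation matrix; and a
  phenome-wide screen regressing every variable on a target marker
  (log-transform, z-standardize both sides, OLS slope as effect size
  ES, Benjamini–Hochberg adjusted two-sided p).
* **Mixed-model association** — per-gene differential expression
  `y = μ + xβ + u + ε` with `u ~ N(0, σ_g²K)`, where the kinship
  `K = MᵀM/p` is the sample covariance of the iteratively
  row/column-standardized expression matrix. The variance ratio
  `δ = σ_e²/σ_g²` is REML-profiled on the eigenbasis of `K`
  (one rotation per scan, grid-then-Brent), with Wald tests, genomic
  inflation reporting, and BLUP-based sample ranking
  (`K(K + δI)⁻¹` shrinkage of residuals).
* **Differential correlation** — per-gene transcript–protein Spearman
  rho by genotype group, gene-level and sample-level concordance
  medians, and the diagonal distance
  `d = (ρ_def − ρ_ctrl)/√2` with Fisher-z difference tests.
* **Isotope tracing** — internal-standard-normalized isotopologue
  fractions, the M+5/M+4 citrate ratio (reductive-carboxylation
  index), a discrete-turn TCA label-propagation simulator with
  parameters `r` (reductive flux), `a` (unlabeled anaplerotic inflow),
  `e` (tracer enrichment), least-squares inversion of `r` from
  observed citrate spectra, Wilcoxon pool comparisons, and
  hypergeometric metabolite-set enrichment.
* **AP-MS** — two-peptide/99% identification thresholds, bait–prey
  presence matrices, Venn partitions, control-exclusive prey
  selection, per-protein one-way ANOVA enrichment at nominal p < 0.05,
  and a weighted bait–prey network (TSV + GraphML).
* **Variant triage** — hard filters (population AF < 0.01; ≥2+2
  strand reads and ≥8 coverage; non-synonymous consequence or P/LP
  class or dbscSNV > 0.6) with a per-rule audit trail, biallelic
  diagnosis calls, allele-class census, mutational burden, and a
  robust-z expression-outlier screen.

`run_pipeline()` executes all stages in dependency order on a cohort
bundle and writes TSV/JSON outputs plus a digest-bearing run manifest.

## Worked example

```r
library(mmaomics)

bundle <- simulate_cohort(cohort_config(n_case = 20, n_control = 10,
                                        n_other = 10, n_genes = 300,
                                        seed = 1))
run <- run_pipeline(bundle, "demo_out")
res <- run$results

head(res$screen_pi_plus, 5)
#>               variable         ES            p        p_adj n_used
#> 1                   PI  0.8129781 1.858303e-10 3.530776e-09     40
#> 2        MMUT_activity  0.7557776 1.721179e-08 1.635120e-07     40
#> 3 carnitine_supplement -0.7386248 5.297437e-08 3.355043e-07     40
#> 4           mma_plasma -0.7180886 1.825295e-07 8.670149e-07     40
#> 5              ammonia -0.7034347 4.139560e-07 1.573033e-06     40
```

The PI+ screen recovers the planted severity structure: the strongest
markers are the sibling in-vitro assays (PI, MMUT activity, positive
ES — they rise and fall together), followed by treatment need and
biochemical derangement with negative ES (sicker patients, lower PI+).
Twelve of nineteen variables are significant at adjusted p < 0.05.

```r
res$cross_level$median_gene      # 0.29  median per-gene rna~protein rho
res$cross_level$median_sample    # 0.13  median per-sample rho

aggregate(m5_m4_ratio ~ condition, res$citrate_ratios, mean)
#>    condition m5_m4_ratio
#> 1    control   0.2100966
#> 2  deficient   0.4625737
```

The M+5/M+4 citrate ratio roughly doubles in the MMUT-deficient
condition — the reductive-carboxylation shift the tracing generator
plants (`r` 0.10 → 0.35) and the fitter recovers per sample in
`res$r_fits`.

```r
length(res$specific)     # 12 preys in all experimental baits, never in controls
nrow(res$calls)          # 25 biallelic diagnoses; recall 1.00 vs bundle$truth
res$allele_counts
#>   missense truncating   splicing
#>         25         18          7
```

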