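---
title: "Models and methods behind mmaomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mmaomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmaomics)
```

`mmaomics` packages the computational core of a multi-omics workup of
methylmalonic aciduria (MMA): phenome-wide severity-marker screening,
kinship-aware mixed-model differential expression, transcript–protein
differential correlation, [U-¹³C]glutamine isotopologue analytics with a
forward TCA labeling model, affinity-purification MS (AP-MS) bait–prey
specificity logic, and rule-based variant triage. Because patient-level
multi-omics data of this kind are access-restricted, the package ships a
seeded synthetic cohort generator that reproduces the statistical
structure each stage assumes; every stage is validated against that
generator plus independent oracles. This vignette explains the models,
the tunable parameters and their defaults, the numerical choices, and
what the synthetic validation does and does not establish.

## Phenomics: severity score and marker screen

The clinical severity score (CSS, `compute_css()`) is the sum of five
binary indicators — early onset, neurological abnormalities, kidney
impairment, hematological abnormalities, failure to thrive — giving an
integer in 0–5. Missing components contribute 0 and are counted in a
completeness attribute rather than imputed: a partially documented
patient can only be under-scored, never over-scored, and the consumer
can weigh completeness explicitly. `early_onset_flag()` binarizes onset
age at 28 days (the neonatal period), configurable.

`correlation_matrix()` uses Spearman rank correlation for *every*
variable-type combination, including binary–binary pairs (where it
equals a rank phi coefficient). One coherent estimator keeps the mixed
matrix interpretable; pairwise-complete deletion (minimum 3 pairs per
cell) avoids imputation assumptions. Cells involving a variable that is
constant on the complete pairs are reported missing with a warning.

`association_screen()` regresses each phenotype variable on a target
(CSS or PI+, the propionate-incorporation assay with hydroxocobalamin),
one variable at a time. Strictly positive continuous variables are
log-transformed first — assay readouts and metabolite concentrations
are ratio-scaled — and variables containing zeros or negatives fall
back to `log1p` with a single consolidated warning. Both sides are then
z-standardized, so the reported effect size (ES) is a standardized
slope comparable across variables; this also makes the ES invariant to
a change of units (a multiplicative rescaling) of any positive
variable. P-values are Benjamini–Hochberg adjusted across the screened
set (`bh_adjust()`, delegating to `stats::p.adjust` and cross-checked
in the tests against a from-scratch step-up oracle), and significance
is counted at adjusted p < 0.05.

## Mixed-model association with expression-derived kinship

Fibroblast cohorts collected over decades carry latent structure
(batches, relatedness of referral centers, culture age). Rather than
model those covariates explicitly, the association engine borrows the
genetics playbook: a random effect with the covariance of the
expression data itself.

Per gene the model is

$$ y = \mu + x\beta + u + \varepsilon,\qquad
   u \sim N(0, \sigma_g^2 K),\quad \varepsilon \sim N(0, \sigma_e^2 I), $$

where $y$ is the rank-inverse-normalized response
(`rank_inverse_normal()`, $\Phi^{-1}((r-0.5)/n)$ with average ranks for
ties, so the normality assumption holds for skewed assay readouts), $x$
the standardized expression of one gene, and $K$ the sample–sample
covariance $K = M^\top M / p$ of the doubly standardized expression
matrix $M$ (`sample_kinship()`).

**Double standardization.** `iterative_standardize()` alternates column
and row z-scoring until both margins have mean 0 and variance 1. A
subtle point drives a deliberate choice: with the sample-variance
convention (denominator $n-1$) the two margin constraints are
inconsistent for non-square matrices — the total sum of squares would
have to equal both $p(n-1)$ and $n(p-1)$ — and the alternation stalls
just short of either target. The package therefore uses population
variance (denominator $n$) throughout, under which both margins imply a
total of $np$ and the procedure converges quickly (tolerance $10^{-6}$
on means, $10^{-5}$ on variances, at most 100 sweeps; seeded 20×15
log-normal matrices converge in well under 50). A convenient corollary
is that $K$ then has an exactly unit diagonal.

**Estimation.** The variance ratio $\delta = \sigma_e^2/\sigma_g^2$ is
profiled on the eigenbasis of $K$: one eigendecomposition rotates the
problem so every candidate $\delta$ costs only $O(n)$, a 41-point grid
on $\log\delta \in [-10, 10]$ brackets the optimum and Brent's method
refines it. REML is the default criterion (unbiased variance
components; ML via `reml = FALSE`); the fixed effect gets a two-sided
Wald test. With $K = I$ the fit collapses analytically onto ordinary
least squares, which the tests exploit as a closed-form oracle
(agreement to $10^{-6}$ in p). The profile optimum can legitimately sit
at a boundary (all variance genetic or none); this is flagged
(`at_bound`), not an error. P-values are invariant to rescaling $K$ by
a positive constant because $\delta$ re-absorbs the scale.

`lmm_scan()` reuses one rotation across all genes of a layer; genes are
standardized before use as fixed effects so slopes are on a common
effect-size scale. The scan reports the genomic inflation factor; on
null simulations (500 genes, 100 samples) calibration stays within
[0.8, 1.25] and the type-I error at nominal 0.05 within [0.035, 0.065],
checked in the test suite at exactly those bands.

`predict_blup()` implements the sample-selection construction: fit the
response on a small fixed design (e.g. GLUD1 and OGDH protein
expression) plus the kinship random effect, and rank samples by
$\hat y = X\hat b + \mathrm{BLUP}(u)$ with
$\mathrm{BLUP}(u) = K(K + \delta I)^{-1}(y - X\hat b)$. With the random
effect switched off it reduces to the OLS prediction; with $K = I$ and
an intercept-only design it shrinks centered responses by
$\sigma_g^2/(\sigma_g^2 + \sigma_e^2)$ — both limits are unit tests.

## Transcript–protein differential correlation

`cross_level_summary()` reports the two standard concordance numbers:
per-gene Spearman correlation across samples and per-sample correlation
across shared genes, with medians. Only genes present in both layers
are used for both directions. `paired_correlation_table()` computes
per-gene correlations separately in MMUT-deficient and control samples
and the signed diagonal distance

$$ d = (\rho_{\text{def}} - \rho_{\text{ctrl}})/\sqrt{2}, $$

the displacement from the equal-correlation diagonal of the
case-vs-control scatter. Spearman p-values use the t-approximation, or
the exact permutation distribution over all $n!$ orderings when a group
has at most 9 samples (the cutoff keeps exact enumeration under half a
second). The difference between two correlations is tested by Fisher's
z transform — the method is not canonical, so a label-permutation
alternative is exercised in the tests; at $n = 30$ per group the two
agree to well within an order of magnitude but not always within a
factor of two, which is expected since Fisher's z is calibrated for
Pearson rather than rank correlations.

## Isotope tracing and the TCA labeling model

`isotopologue_fractions()` converts peak areas to fractions: areas are
normalized to the sample's matching-polarity internal standard, missing
isotopologues are imputed as zero area, and each (sample, metabolite)
block is scaled to sum to 1 over M+0..M+n with n the metabolite's
carbon count. No natural-abundance correction is applied — the
upstream workflow this mirrors used none — but fractions are a
per-metabolite simplex so any such correction could be slotted in
before normalization. The M+5/M+4 citrate ratio (`citrate_ratio()`)
indexes reductive carboxylation relative to oxidative turning under
[U-¹³C]glutamine.

`simulate_labeling()` is a discrete-turn propagation model, not an ODE
flux model: the biological claims it supports are pattern-level (M+4
versus M+5 citrate, M+0 dilution), and a turn-based model reproduces
those with identifiable parameters. Three parameters, each a fraction
in [0, 1]:

* `r` — reductive flux: share of oxoglutarate carboxylated directly to
  citrate (M+5 preserved) instead of turning oxidatively
  (decarboxylation to the 4-carbon pool, M+5 → M+4);
* `a` — unlabeled anaplerotic inflow at succinyl-CoA (the
  methylmalonyl-CoA entry), diluting the labeled 4-carbon pool;
* `e` — ¹³C enrichment of the glutamine source.

Carbon loss uses the random-carbon rule (an M+i species loses a labeled
carbon with probability $i/n$), which is exact at the fully labeled
endpoints that anchor the hand-checkable identities: at
`r = 0, a = 0, e = 1, turns = 1` citrate and succinate are pure M+4; at
`r = 1` citrate is pure M+5; at `a = 1` the 4-carbon pool is pure M+0.
Later turns recycle citrate back to oxoglutarate, diluting label by
convolution with unlabeled acetyl-CoA; reported spectra average over
turns, emulating a pool fed continuously across cycles. The default
`turns = 3` is enough for the dilution patterns to stabilize while
keeping the single-turn identities testable. The citrate ratio is
strictly increasing in `r` (checked on a 21-point grid) and M+0 of the
4-carbon metabolites strictly increasing in `a`, which is the mechanism
behind the reduced M+0 fractions expected when the methylmalonyl-CoA
anaplerotic entry is lost.

`fit_reductive_fraction()` inverts the model by least squares on the
citrate spectrum (coarse grid, step 0.02, then Brent refinement),
recovering `r` to $10^{-3}$ noiselessly and to within 0.05 in the mean
under fraction noise of sd 0.02; a near-flat objective is flagged
non-identifiable. Pool-size contrasts use the two-sided Wilcoxon
rank-sum test (exact for small tie-free groups) and metabolite-set
enrichment the upper-tail hypergeometric test with BH adjustment, both
through the standard `stats` routines and both cross-checked against
exhaustive enumeration in the tests.

## AP-MS specificity and enrichment

Identification follows the classic two-peptide rule
(`apply_id_thresholds()`): a protein is present in a run when its
protein probability exceeds 0.99 and at least two peptides individually
exceed 0.95. "Pulled down by a bait" means detected in at least one
replicate of that bait (`min_replicates` exposes the inclusion side;
the exclusion side — no detection in *any* control replicate — is
strict). `specific_prey()` implements the Venn-style specificity
filter: detected in at least `min_required` of the experimental baits
and never in a forbidden (control) bait; it is monotone in both
thresholds, and together with `venn_partition()` is tested against
brute-force enumeration on random presence tensors. Enrichment uses a
per-protein one-way fixed-effects ANOVA across the bait and control
triplicates at a nominal p < 0.05 without multiplicity adjustment —
deliberately, as the downstream network is an exploratory candidate
list, not a confirmatory claim. `build_network()` draws one edge per
(bait, enriched prey) weighted by $-\log_{10} p$ and annotates nodes as
bait, control-exclusive prey, or shared prey; GraphML export is
included for network tools.

## Variant triage

`filter_variants()` applies three conjunctive rule blocks with a
per-rule audit trail: frequency (maximum population allele frequency
< 0.01), read support (≥2 forward and ≥2 reverse reads, ≥8 coverage;
copy-number variants come from a separate caller and bypass read
support but not frequency), and relevance (non-synonymous coding
consequence, or a pathogenic/likely-pathogenic ClinVar/InterVar class,
or a dbscSNV ADA/RF splice score > 0.6). The filter is monotone:
loosening any threshold never removes a passing record.
`biallelic_calls()` issues a diagnosis per (individual, gene) for a
passing homozygous allele or ≥2 distinct passing heterozygous alleles;
phase is unknown, so compound heterozygosity assumes trans — a
documented limitation shared with any trio-free design — and both
alleles must pass the filter (a non-passing partner does not rescue a
lone het). The allele census doubles homozygous calls; totals conserve
by construction. `mutational_burden()` lists genes with biallelic calls
in ≥2 individuals. `expression_outlier()` is a deliberately simple
stand-in for dedicated aberrant-expression callers: per-gene robust z
(median/MAD) with a default under-expression threshold of −3; genes
with zero MAD are skipped with a warning.

## The synthetic cohort generator

`simulate_cohort()` draws every table from one master seed, split into
named per-layer sub-seeds so layers can be regenerated independently;
`truth` records all generating parameters. Defaults, chosen once as the
study conditions and not tuned afterwards:

* **Severity axis.** Latent severity is standard normal
  (`severity_sd = 1`), with the MMUT-deficient group shifted +1 sd and
  other-MMA +0.5 sd — the simplest structure that makes a few variables
  predict many. Phenotypes load linearly on severity (binary variables
  through a logistic link); assay-like variables are exponentiated so
  they are strictly positive and log-normal, matching the screen's log
  transform. PI/PI+ load negatively (−0.8/−0.9), biochemical markers
  positively, and five null variables carry no signal.
* **Expression.** Base abundance is log-normal; effects are log2 fold
  changes applied to MMUT-deficient samples then exponentiated. The
  default effect table is MMUT −1.5/−1.5 (RNA/protein), OGDH −0.3/−0.8,
  GLUD1 +0.3/+0.8, ALDH2 +0.5/+0.5, PDK4 +0.8/+0.2 — the qualitative
  pattern of MMUT deficiency. Protein couples to the standardized
  transcript with coefficient `c` (default 0.3) plus
  $\sqrt{1-c^2}$-scaled independent noise, so the per-gene
  transcript–protein Spearman correlation follows the Gaussian arcsine
  relation $(6/\pi)\arcsin(c/2)$.
* **Tracing.** Control cells simulate at `r = 0.10, a = 0.45`;
  deficient cells at `r = 0.35, a = 0.15` (loss of the
  methylmalonyl-CoA entry lowers unlabeled inflow and raises reductive
  preference), `e = 0.9`, `turns = 3`, fraction noise sd 0.02, and
  halved TCA pool sizes in the deficient condition.
* **AP-MS.** Four experimental baits and two negative controls in
  triplicate; 12 specific preys present only in experimental
  pull-downs, 40 background proteins everywhere at random, an 8-fold
  intensity enrichment of specific preys in the target bait, plus
  sub-threshold records that exercise the identification rules.
* **Variants.** Every MMUT-deficient individual gets a passing
  biallelic MMUT genotype (30% homozygous) with consequence classes
  drawn at missense/truncating/splicing/in-frame/CNV weights
  0.56/0.35/0.07/0.01/0.01 — the approximate allele-class composition
  reported for large MMUT cohorts; half the other-MMA individuals get
  biallelic ACSF3/TCN2/SUCLA2/MMAB genotypes. Noise alleles each
  violate exactly one filter (common, weak read support, synonymous),
  or pass as a partnerless het in a gene of its own.

What passing on this generator shows: the estimators recover the
parameters they target under the stated noise models, the decision
rules match their specifications exactly, and the pipeline is
deterministic and internally consistent. What it does not show:
robustness to real-data pathologies the generator does not emulate —
batch effects, missing-not-at-random phenotypes, heavy-tailed
proteomics noise, linkage between variants, or annotation errors.
Cohort-scale headline numbers from the original clinical material
(diagnostic yield, specific marker counts, cross-level correlation
medians) depend on access-restricted data and are not reproduced here.

## Problem sizes and determinism

The shipped validation uses desk-scale sizes chosen to exercise every
code path with comfortable statistical resolution: null calibration
with 2,000 single fits and a 500-gene scan at 100 samples, effect
recovery over 200 replicates at 200 samples, and an end-to-end demo at
40 samples × 800 genes. All randomness flows from explicit seeds;
rerunning any stage with the same inputs reproduces byte-identical
outputs, which the run manifest verifies by file digest.
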