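# grsroc

Multi-marker genetic risk score (GRS) analysis for case-control genotype
studies, with nonparametric ROC/AUC comparison of predictors.

The package is aimed at analysts of candidate-gene or small-panel
case-control studies of complex disease — the motivating setting is a
five-marker psoriasis susceptibility panel (an HLA class-I presence allele,
a biallelic deletion CNV, and three SNPs) — who want to go from a per-sample
risk-allele dosage table to a complete, reproducible report: per-marker
association, aggregate risk scores, and a formal comparison of how well each
predictor separates cases from controls.

## What it computes

For a cohort of samples with status (case/control), sex, age and additive
risk-allele dosages `g_im ∈ {0, 1, 2}` over M markers:

- **Allelic association** per marker from the 2×2 allele-count table
  (a, b; c, d): crude odds ratio `OR = ad/bc` with the Wald 95% CI
  `exp(log OR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`, plus sex/age-adjusted ORs
  `exp(β_m)` from a joint logistic model
  `logit P(case) = β₀ + Σ_m β_m g_im + β_sex·sex + β_age·age`,
  and an exact conditional Hardy–Weinberg test per status group.
- **Count GRS** `cGRS_i = Σ_m g_im` and **weighted GRS**
  `wGRS_i = Σ_m ln(OR_m)·g_im`, with group descriptives
  (mean, SD, median, Tukey-hinge IQR) and two-sided Mann–Whitney
  comparisons of cases vs. controls.
- **ROC/AUC** for every predictor (each single marker, cGRS, wGRS):
  the Mann–Whitney AUC
  `Â = (1/n₁n₀) Σ_ij ψ(s_i, s_j)` (ψ = 1 / ½ / 0 for win/tie/loss),
  DeLong structural-component variances, and paired DeLong z-tests for
  every pair of predictors scored on the same samples.
- **Synthetic cohorts**: a generator that draws Hardy–Weinberg genotypes,
  assigns status by a logistic disease model with configurable per-allele
  ORs and prevalence, samples a retrospective case-control cohort and
  injects genotyping dropout — so the whole pipeline is testable and its
  estimators can be validated by parameter recovery.

Samples missing any marker genotype are removed by a complete-case filter
before any score is computed, and the exclusion counts are logged.

## Worked example

```r
library(grsroc)
set.seed(7)
cohort <- simulateCohort(simConfig())   # default study conditions
cohort
#> GenotypeCohort: 5 markers x 294 samples
#>   cases: 148  controls: 146
#>   markers: HLA-C*06, rs26653, LCE3C_LCE3B-del, rs17589, rs17695937
#>   missing dosages: 71 (4.8%)

report <- runFullAnalysis(cohort, zeroCellCorrection = TRUE)
#> input: 148 cases, 146 controls, 5 markers
#> baseline: sex Fisher p = 0.128967, age Mann-Whitney p = 0.889734
#> complete-case filter: removed 27 cases and 36 controls; 121 cases, 110 controls retained
#> association: crude ORs HLA-C*06=6.38, rs26653=2.38, LCE3C_LCE3B-del=1, rs17589=1.28, rs17695937=1.38
#> weights (crude, log base 2.718): HLA-C*06=1.8524, rs26653=0.8659, LCE3C_LCE3B-del=0.0019, rs17589=0.2487, rs17695937=0.3243
#> cGRS: case mean 3.893 vs control mean 2.645 (p = 1.631e-08)
#> wGRS: case mean 2.729 vs control mean 1.223 (p = 1.53115e-15)
#> AUC: HLA-C*06=0.752, rs26653=0.648, LCE3C_LCE3B-del=0.502, rs17589=0.540, rs17695937=0.559, cGRS=0.712, wGRS=0.804
report
#> GRSReport
#>   markers: 5  predictors in AUC table: 7  pairwise tests: 21
#>   complete-case samples scored: 231
#>   cGRS: case mean 3.89 vs control mean 2.65 (Mann-Whitney p = 1.63e-08)
#>   wGRS: case mean 2.73 vs control mean 1.22 (Mann-Whitney p = 1.53e-15)
```

Reading the output: both scores are clearly shifted upward in cases, the
weighted score more so (smaller Mann-Whitney p), and the wGRS AUC (0.804)
exceeds both the count score (0.712) and the best single marker (the HLA
allele, 0.752) — the weighting by ln(OR) concentrates discrimination in the
informative markers. `report@comparisons` holds the 21 pairwise DeLong
tests; `writeReport(report, "out/")` writes every table plus a text summary
and a run manifest.

File-based workflows use `readMarkerPanel()` / `readDosageTable()` /
`writeDosageTable()` (tab-separated, dosages 0/1/2 with `NA` for dropouts;
a small synthetic example ships under `inst/extdata/`), or the thin CLI at
`inst/scripts/grsroc-pipeline.R` with `simulate` and `analyze` subcommands.

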