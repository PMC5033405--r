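---
title: "Genetic risk scores and correlated-AUC comparison: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores and correlated-AUC comparison: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The setting

A retrospective case-control study genotypes each participant at a small
panel of susceptibility markers and asks two questions: how strongly is each
marker associated with disease, and how well does the panel as a whole —
summarised in a per-individual genetic risk score — separate cases from
controls, compared with any single marker? `grsroc` implements that analysis
for additively coded biallelic markers. The motivating application is a
five-marker psoriasis panel in which an HLA class-I presence allele, a
deletion CNV spanning two late-cornified-envelope genes, and three SNPs are
all reduced to risk-allele dosages 0/1/2; the dosage coding is deliberately
uniform across marker classes (the HLA genotyping distinguishes homozygous
from heterozygous carriers, and the deletion is biallelic), so the marker
class is pure metadata.

```{r, message = FALSE}
library(grsroc)
set.seed(1)
cohort <- simulateCohort(simConfig(nCases = 120, nControls = 120))
cohort
```

## The cohort container and the complete-case filter

`GenotypeCohort` extends `SummarizedExperiment`: the `dosage` assay holds
markers × samples integer dosages with `NA` for a failed genotype, `colData`
the status/sex/age covariates, `rowData` the marker panel. Validity rules
enforce dosages in {0, 1, 2, NA}, binary status and sex, positive age, and
unique sample and marker identifiers.

A sample missing any marker genotype cannot be scored, so
`completeCaseFilter()` removes it before any downstream computation, records
how many cases and controls were lost, and never alters a retained value.
The filter is idempotent and applied exactly once by the pipeline. Whether
*per-marker* association should use all samples genotyped at that marker or
only the complete-case set is genuinely ambiguous in practice; the package
defaults to the complete-case set (so every reported quantity describes the
same samples) and exposes `perMarker = TRUE` for the more inclusive
alternative.

## Per-marker association

Allelic association treats the 2 × 2 table of *allele* counts (rows:
case/control, columns: risk/other allele), so a cohort of $n_1$ cases
contributes $2 n_1$ alleles. The crude OR is $ad/bc$ with the Wald interval
$\exp(\log OR \pm z_{0.975}\sqrt{1/a+1/b+1/c+1/d})$. Zero cells make the
estimate degenerate; the package raises an error by default and applies the
Haldane–Anscombe +0.5 correction (to all four cells) only behind an explicit
flag, because a silent correction would invisibly change a published-style
estimate. Wald intervals are used throughout; profile-likelihood intervals
are out of scope.

Adjusted ORs come from one joint ("multivariate") logistic model containing
all panel dosages plus sex (binary) and age (linear, years), fitted by IRLS
(`stats::glm`) with convergence tolerance `1e-8` and at most 100 iterations.
No interactions are modelled. The fit is checked after the fact: the score
vector must vanish numerically at the optimum and no coefficient may exceed
15 in absolute value (the signature of separation); violations flag
`converged = FALSE` rather than failing silently.

Genotyping quality is checked per marker and status group with an **exact
conditional Hardy–Weinberg test**: conditioning on $n$ and the allele count
$n_A$, $P(n_{Aa} = h) \propto n!/(n_{AA}!\,n_{Aa}!\,n_{aa}!)\cdot 2^h$ over
heterozygote counts of matching parity, and the p-value sums all
configurations no more probable than the one observed. The exact test is
chosen over the chi-square approximation because expected rare-homozygote
counts are small at $n \approx 100$–$150$. Baseline comparability uses
Fisher's exact test for sex (probability-mass two-sided rule, the
`fisher.test` convention) and the Mann–Whitney test for age.

## The two risk scores

With weights $w_m$ the weighted score is $\mathrm{wGRS}_i = \sum_m w_m
g_{im}$; the count score is the special case $w_m = 1$, an identity the
tests assert exactly. Weights default to $\ln OR_m$ estimated in-sample
(crude by default, adjusted optionally); externally estimated ORs may be
supplied for honest out-of-sample scoring, and negative weights (protective
alleles) are permitted.

The **natural** logarithm is the default weight scale. For the default
five-OR panel (7.42, 2.26, 1.19, 1.12, 1.05) the maximum attainable score is
$2\sum_m \ln OR_m = 6.31$; a base-10 scale would compress the same range to
2.74. Published wGRS summaries in this study design are only consistent with
the natural-log range (reported case means exceed the base-10 ceiling), so
base e is the default; `logBase` remains configurable, and every rank-based
statistic downstream (Mann–Whitney, ROC/AUC, DeLong) is invariant to the
choice because it is a positive rescaling.

Descriptives report mean, SD ($n-1$), median, and IQR. The IQR uses **Tukey
hinges** (`fivenum`) by default — commercial packages are ambiguous about
their quantile rule, so the rule is stated and configurable
(`quantileType`). A singleton group reports SD 0, flagged by its $n$.

The Mann–Whitney comparison is two-sided, exact by full enumeration when
$n_1 + n_2 \le 16$ and tie-free, and otherwise uses the normal approximation
with tie-corrected variance and **no** continuity correction. Ties always
use the ½ kernel — essential here, since a 5-marker count score has only 11
attainable values.

## ROC, AUC and the DeLong comparison

The empirical ROC enumerates all distinct thresholds (tied scores share a
point); the AUC is computed as the Mann–Whitney statistic, which equals the
trapezoidal area exactly — the suite asserts agreement to $10^{-12}$ on a
thousand random, heavily tied instances. Predictors are oriented so that
higher values are more case-like, and no automatic flip is performed: an
AUC below 0.5 is reported as-is rather than silently inflated.

DeLong's structural components are $V^{10}_i$ (case $i$'s mean kernel
against all controls) and $V^{01}_j$; single-AUC variance is
$S_{10}/n_1 + S_{01}/n_0$ with $n-1$ sample (co)variances, and the paired
test of predictors $a, b$ on identical samples uses
$z = (\hat A_a - \hat A_b)/\sqrt{S_{11}+S_{22}-2S_{12}}$ against the
standard normal, two-sided, with no small-sample correction. Two identical
predictors have exactly zero contrast variance; that degenerate case returns
$z = 0$, $p = 1$ by convention. The implementation is validated three ways:
bootstrap SEs (stratified, 2000 resamples) within 15%, an independent
implementation (pROC) to near machine precision, and rank-invariance under
monotone transforms.

```{r, message = FALSE}
report <- runFullAnalysis(cohort, zeroCellCorrection = TRUE)
report@auc
```

## The synthetic cohort generator

Because individual-level genotypes from such studies are typically not
deposited, the generator is a first-class module: it defines the conditions
under which the pipeline is exercised and validated.

The generative model: each marker's dosage is Binomial(2, $f_m$) — i.e.
Hardy–Weinberg proportions — independently across markers (the default
panel's loci lie in different genomic regions, so no LD is modelled); sex is
Bernoulli(0.55) and age is normal(43, 14²) truncated below at 18 years,
echoing the demographic profile of a single-centre adult dermatology cohort;
disease status follows
$\mathrm{logit}\,P(case) = \beta_0 + \sum_m \ln(OR_m) g_m$ (sex and age
effects default to 0, as the motivating study found no case-control
difference in either), with $\beta_0$ solved deterministically (root-finding
to $10^{-10}$) so that the *population mean* case probability equals the
target prevalence. A population of 20× the requested cohort is simulated and
the case/control strata are subsampled without replacement — exactly the
retrospective design; an undersized stratum is a hard error naming the
remedy. Finally, each dosage is independently blanked at the missingness
rate.

Default parameter choices, made once:

| parameter | default | rationale |
|---|---|---|
| true ORs | 7.42, 2.26, 1.19, 1.12, 1.05 | one strong HLA effect plus weak modifiers, the structure GRS methods must cope with |
| control allele freqs | 0.10, 0.35, 0.30, 0.25, 0.40 | synthetic placeholders giving realistic score ranges; **not** population estimates |
| prevalence | 0.05 | psoriasis affects 2–4% of Caucasians, more in northern Europe |
| missingness | 0.05/marker | complete-case retention $0.95^5 \approx 0.77$, matching the ~77% retention typical after multi-marker PCR genotyping |
| cohort | 148 cases / 146 controls | the study scale the pipeline targets |

What the generator does **not** emulate: linkage disequilibrium, epistasis,
population stratification, relatedness, genotyping error (as opposed to
dropout), and informative missingness. Passing tests therefore demonstrate
the estimators' correctness and calibration under a clean additive logistic
world — not robustness to confounding or cryptic structure in real data.

## Validation strategy and problem sizes

The acceptance-level tests pin down, at sizes chosen to keep the suite
fast while statistically meaningful: the ROC/Mann–Whitney identity (1000
instances, tolerance $10^{-12}$); exact-test agreement with brute-force
enumeration (every HWE configuration to $n = 50$; all 2×2 tables to total
12 plus random tables to total 40; all Mann–Whitney group sizes to 7);
DeLong vs. bootstrap SEs on a 200/200 cohort; Wald CI coverage of the true
log-ORs within 93–97% over 500 cohorts of 1000/1000 with mean bias ≤ 0.05
on the two largest effects; and, at the published study scale (126/100,
100 replicates), the expected dominance ordering AUC(wGRS) ≥ AUC(cGRS) and
AUC(wGRS) > every single marker in ≥ 90% of replicates. End-to-end
determinism (simulate + analyze byte-identical under a fixed seed) is
asserted on written files.

## Known limitations

- Wald intervals (crude and adjusted) undercover for very sparse tables;
  the zero-cell flag mitigates but does not remove this.
- The DeLong z-test relies on asymptotic normality; with very few cases or
  near-perfect AUCs its p-values become conservative or anti-conservative.
- In-sample weights make the wGRS optimistic (weights and scores estimated
  on the same cohort, as is common in small panels); external weights are
  the honest alternative and are supported.
- The exact Mann–Whitney mode refuses ties; tied data always use the
  tie-corrected approximation, which is approximate at very small n.
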