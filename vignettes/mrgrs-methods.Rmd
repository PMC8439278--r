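---
title: "Risk-score Mendelian randomization: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-score Mendelian randomization: models, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrgrs)
```

## The analysis this package implements

`mrgrs` implements a Mendelian randomization (MR) design for a binary
exposure (type-2 diabetes, T2DM, in the motivating application) and a binary
disease outcome (lung cancer), on individual-level genotype dosages. The
exposure is never observed in the analysis cohort; instead it is *genetically
predicted* by a weighted genetic risk score over a set of independent
exposure-associated variants with published per-allele effects:

\[
\mathrm{wGRS}_s = \sum_{i} \beta_i \, \mathrm{SNP}_{si},
\]

where \(\beta_i\) is the published exposure log-odds ratio of variant *i*
and \(\mathrm{SNP}_{si}\) the dosage (0–2) of its effect allele in sample
*s*. The disease model is a logistic regression of case status on the score,
adjusted for age group, sex, smoking status and ten principal components,
fitted per dataset and pooled by inverse-variance meta-analysis. Because
alleles are randomized at conception, the score is independent of classical
confounders of the exposure–outcome relationship, and an association between
the score and the disease is evidence of a causal effect of the exposure —
provided the instruments act on the outcome only through the exposure.

That exclusion-restriction assumption is probed with summary-statistic
estimators: inverse-variance weighted (IVW), MR-Egger (whose intercept
estimates average directional pleiotropy), and the simple and weighted
median estimators, which tolerate up to half invalid weight.

## Instrument selection

`select_instruments()` applies the selection rules in a fixed order:
non-autosomal variants are removed; variants below a reference-panel minor
allele frequency floor (default 0.01) are removed; indels are replaced by
their best proxy SNP in the panel at \(r^2 > 0.40\) (the proxy inherits the
published effect, oriented by the sign of the dosage correlation, since no
re-estimation is available for a substituted proxy); the remaining variants
are greedily pruned to pairwise \(r^2 < 0.10\). LD is the squared Pearson
correlation of unphased dosages — the standard composite estimator when
haplotype phase is unavailable. Greedy pruning visits variants in order of
exposure p-value so that the better-supported member of a correlated pair is
always retained; ties break lexicographically by rsid to keep the output
deterministic. Selection is idempotent, and the report's dispositions
reconcile exactly with the input count.

When several panel SNPs exceed the proxy threshold, the highest-\(r^2\) SNP
is taken — with no record of which LD partner an upstream pipeline chose,
"best available" is the only deterministic rule.

## Quality control

Variant filters (call rate ≥ 0.95, control MAF ≥ 0.005, and Hardy–Weinberg
equilibrium floors of \(10^{-5}\) in all samples, \(10^{-7}\) in controls,
\(10^{-12}\) in cases) are applied in that order, each variant attributed to
the first rule it fails. All three HWE rules are applied jointly; each can
be disabled independently by setting its threshold to `NA`, since QC
pipelines differ on whether the all-sample and per-group rules are
alternatives or cumulative. HWE uses the 1-df asymptotic chi-square test —
adequate at the sample sizes the package targets, and checkable by hand.
Relatedness is consumed as a precomputed PI_HAT table (estimating
identity-by-descent is upstream tooling); from each pair above 0.25 the
lower-call-rate member is dropped. Heterozygosity outliers beyond 6 SD of
the cohort mean are removed. Fractional dosages are rounded to hard calls
for the HWE and heterozygosity computations only.

## Score construction and harmonization

Effect alleles are matched to genotype records by direct match, allele swap,
strand flip, or both; palindromic (A/T, C/G) variants are resolved by
comparing allele frequencies, with an ambiguity band of 0.42–0.58 in which
they are refused (or dropped under `drop_palindromic`). Missing dosages are
imputed as twice the control-group effect-allele frequency, keeping the
sample size constant across variants; in imputed dosage data missingness is
rare, so the choice is immaterial in practice but keeps the score defined
for every sample.

The headline odds ratio is reported per control-group standard deviation of
the score (`standardize = TRUE`), the conventional reporting unit for risk
scores; the per-weighted-allele scale is available by turning
standardization off. Published risk-score odds ratios frequently omit the
unit, so both scales are exposed.

## Logistic engine and inference

`fit_logistic()` is maximum likelihood by iteratively reweighted least
squares (relative deviance change below \(10^{-10}\), at most 25
iterations), with Wald standard errors from the inverse observed
information. All 95% intervals use the fixed constant \(z = 1.959964\).
Quasi-separation is flagged when any coefficient exceeds 15 in absolute
value; such fits return no estimate rather than a misleading one, since
degenerate strata are expected in small simulated runs. Rank-deficient
designs are fatal and name the collinear columns. Strata with a single
outcome class are skipped with a warning. Per-SNP disease associations are
declared significant only at the Bonferroni level \(0.05/m\) for *m*
instruments.

## Meta-analysis and heterogeneity

Per-dataset estimates are pooled with fixed-effect inverse-variance weights;
Cochran's Q (always computed with fixed-effect weights, its standard
definition) tests between-dataset and between-subgroup homogeneity on
\(k-1\) degrees of freedom. Fixed-effect pooling is the headline because the
motivating analyses are homogeneous replications of one protocol; a
DerSimonian–Laird random-effects option is provided for sensitivity. The
number of datasets is fully configurable — the generator defaults to three,
matching the three-study design of the motivating cohorts, but nothing
depends on that count.

## Summary-statistic estimators

With harmonized per-variant pairs \((\hat\beta_{Xi}, \hat\beta_{Yi})\):

* **IVW**: zero-intercept weighted regression of \(\hat\beta_Y\) on
  \(\hat\beta_X\) with first-order weights \(1/\mathrm{se}_{Yi}^2\);
  algebraically identical to the fixed-effect meta-analysis of the ratio
  estimates \(\hat\beta_{Yi}/\hat\beta_{Xi}\). No residual over-dispersion
  scaling is applied (the classical fixed-effect variant).
* **MR-Egger**: the same regression with a free intercept, after
  re-orienting each pair so \(\hat\beta_X \ge 0\) (making the fit invariant
  to allele orientation). The intercept estimates average directional
  pleiotropy. Standard errors carry a multiplicative residual scale bounded
  below by 1.
* **Medians**: the 50% point of the ratio estimates by linear interpolation
  in cumulative weight — equal weights for the simple median,
  \(\hat\beta_{Xi}^2/\mathrm{se}_{Yi}^2\) for the weighted median. Standard
  errors come from a parametric bootstrap (default 1,000 draws) under a
  caller-supplied seed; the caller's RNG state is restored afterwards.

First-order weights ignore exposure-side uncertainty; this matches the
classical estimators and standard MR tooling, and is accurate when
instruments are strong (published GWAS instruments have
\(|\beta_X|/\mathrm{se}_X \gtrsim 6\)). It is a documented limitation for
weak-instrument settings.

## The synthetic cohort generator

Individual-level genotype data of the kind this analysis targets are
access-restricted, so every stage is exercised against `simulate_cohort()`,
which
reproduces the statistical structure the analysis assumes:

* Genotypes are independent Binomial(2, EAF) draws — Hardy–Weinberg by
  construction, no LD between instruments (the real instrument set is
  LD-pruned, so independence is the intended regime).
* A continuous exposure liability \(L = \sum_i \beta_i (g_i - 2p_i) +
  \gamma U + \varepsilon\) with standard-normal noise and optional shared
  confounder *U*; binary exposure status is Bernoulli with
  \(\mathrm{logit}^{-1}(\mathrm{logit}(0.10) + L)\), i.e. ~10% exposure
  prevalence.
* The outcome is **rare**: case probability is logistic in
  \(\mathrm{logit}(0.01) + \theta L + \sum_i \alpha_i (g_i - 2p_i) +
  \gamma U + 0.7\,\mathrm{smoker} + 0.3\,\mathrm{age} \ge 60\), where
  \(\theta\) is the causal effect and \(\alpha_i\) per-variant direct
  (pleiotropic) effects. Rarity is not cosmetic: for a rare outcome the
  marginal per-allele odds ratio essentially coincides with the conditional
  one (log-odds ≈ log-rate, which is collapsible), so the per-SNP logistic
  coefficients estimate \(\theta\beta_i + \alpha_i\) and the ratio
  estimators recover \(\theta\) without non-collapsibility bias. This is
  also the realistic regime for a cancer outcome.
* Case-control sampling is by rejection from batched superpopulation draws,
  preserving the logistic interpretation of all fitted coefficients;
  unreachable case counts fail explicitly after a bounded number of rounds.
* Covariate marginals are Bernoulli(0.5) for age ≥ 60, sex and ever-smoking
  and standard normal for ten PCs, matching the near-50/50 splits of the
  motivating cohorts; case histology is multinomial with adenocarcinoma the
  majority class (66/22/12), matching its reported dominance.
* One global seed drives instrument-level draws; each dataset uses a stream
  derived by a fixed offset, so partial re-runs are reproducible. The
  `truth` record carries every generated parameter.

Default effect-allele frequencies are uniform on (0.05, 0.95). Default
per-allele exposure effects are uniform on (0.10, 0.20) — the magnitude of
genome-wide-significant T2DM lead variants — chosen so that simulated
instruments are strong: the variance explained by the real 82 variants in
the source population is not reported anywhere, so instrument strength is
set for adequate simulated power and for negligible sampling-noise dilution
in the first-order IVW weights, not to match an unknown \(R^2\).

`cohort_to_sumstats()` produces the per-variant summary pairs. Its default
exposure arm (`"published"`) takes \(\hat\beta_X\) from the instrument
table, exactly as the risk-score analysis weights dosages with external
GWAS estimates — a two-sample design in which exposure- and outcome-side
errors are independent. One-sample re-estimation is available on two
scales: `"liability"` (linear regression of the continuous liability on
dosage, full sample — valid because the rare-outcome case tilt is
independent of genotype) and `"status"` (logistic regression of binary
exposure status among controls). The one-sample options carry the usual
finite-sample artifacts (regression dilution of the weights, correlated
errors inflating the Egger slope), which is precisely why the published
scale is the default.

What the generator does **not** emulate: LD between instruments and proxy
haplotype structure, imputation uncertainty, population stratification
(PCs are noise covariates here), or assortative mating. Passing calibration
tests therefore demonstrates correctness of the estimation machinery under
the design's own assumptions, not robustness to violations the real data
might harbor.

## Problem sizes used in the shipped checks

The calibration studies in the test suite use 200 null cohorts of 2,000
cases and 2,000 controls with 82 instruments (nominal 5% rejection of the
score test and Egger intercept test; Bonferroni-clean 82-SNP scans), and 50
cohorts of 10,000 cases and 10,000 controls each for causal-effect recovery
(\(\theta = 0.3\)) and directional-pleiotropy recovery
(\(\alpha = 0.1\)). These sizes give binomial noise on the checked rates
well inside the asserted bands while keeping a full run on one CPU in the
tens of minutes.

## Known limitations

* The Egger intercept inherits a small residual attenuation (order a few
  percent of the pleiotropic effect) from the outcome not being perfectly
  rare; it is visible only at very large simulated sample sizes.
* Exact (permutation/Fisher) alternatives to the asymptotic tests are not
  provided; at the targeted sample sizes the asymptotics are adequate.
* The wGRS arm and the summary-statistic arm share the same cohort, so
  their results are correlated; they are complementary model checks, not
  independent replications.
* X-chromosome instruments are excluded by design, so no dosage-compensation
  model is needed.
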