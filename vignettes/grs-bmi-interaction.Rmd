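---
title: "Genetic risk scores and BMI-by-genetic-risk interaction on biopsy outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores and BMI-by-genetic-risk interaction on biopsy outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsbmi)
```

## The scientific problem

Prostate cancer risk at biopsy depends on both inherited susceptibility and
modifiable factors such as obesity. A standing question in biopsy cohorts is
whether the predictive value of body-mass index (BMI) is uniform, or whether
it is concentrated in men who already carry high inherited risk. `grsbmi`
implements the two pieces needed to ask that question reproducibly:

1. a **population-standardized multiplicative genetic risk score (GRS)**
   built from a panel of risk SNPs with externally derived allelic odds
   ratios, and
2. a **stratified interaction analysis**: GRS tertiles define low /
   intermediate / high genetic-risk strata, per-stratum logistic models give
   adjusted per-unit BMI odds ratios, and a pooled model with BMI-by-stratum
   product terms tests whether the BMI effect differs across strata.

Because real clinical genotype/phenotype data of this kind are not publicly
deposited, the package also ships a **synthetic cohort generator** whose
data-generating process carries exactly the structure the analysis assumes,
so the whole pipeline is testable at desk scale.

## The score

For SNP $i$ with allelic odds ratio $\mathrm{OR}_i$ and risk-allele frequency
$p_i$, the multiplicative model gives genotypic odds ratios
$(1, \mathrm{OR}_i, \mathrm{OR}_i^2)$ for 0, 1, 2 copies of the risk allele.
Hardy–Weinberg equilibrium gives genotype frequencies
$\left((1-p_i)^2,\; 2p_i(1-p_i),\; p_i^2\right)$. The *average risk* in the
population is

$$\bar r_i = (1-p_i)^2 + 2p_i(1-p_i)\,\mathrm{OR}_i + p_i^2\,\mathrm{OR}_i^2,$$

and each genotype's **relative risk** is its genotypic OR divided by
$\bar r_i$. By construction the population expectation of each SNP's relative
risk is exactly 1. A subject's GRS is the product of their per-SNP relative
risks, so for independent SNPs the population mean GRS is 1 and values above
1 mark above-average inherited risk:

```{r}
prof <- snp_risk_profile(list(allelic_or = 1.5, risk_allele_freq = 0.3))
prof$mean_risk
prof$relative_risk
sum(prof$relative_risk * prof$genotype_freq)
```

Design choices in the score, made where the method leaves room:

* **HWE-derived genotype frequencies** from the panel's stated risk-allele
  frequency, not frequencies observed in the analyzed cohort. This keeps the
  score a fixed function of the panel — two cohorts scored with the same
  panel are on the same scale. `snp_risk_profile()` is the single place the
  frequencies enter, so tabulated genotype frequencies could be substituted
  there if a panel supplied them.
* **Missing genotypes** contribute the neutral factor 1 (the
  population-average risk) under the default `missing_policy = "neutral"`,
  the standard convention for this family of scores; `"drop_subject"` is
  available as a sensitivity analysis. Subjects with *no* usable genotype
  are always excluded, with a warning.
* **Log-space accumulation.** Products over large panels are summed as log
  relative risks and exponentiated once, so panels of hundreds of SNPs
  cannot underflow. The score is reported on the natural multiplicative
  scale with a `log_grs` column alongside, since diagnostics conventionally
  use the log score.

## Genotype input and allele bookkeeping

VCF genotypes are matched to the panel by rsid (ID column) with a CHROM+POS
fallback. If ALT is the panel's risk allele the ALT dosage is the count; if
the orientation is flipped (REF is the risk allele) the count is
complemented ($2-$dosage). If the site's alleles match neither orientation
the read **fails** with an allele-mismatch error naming the rsid: silent
strand inference is a known failure mode of risk-score pipelines, so strand
flips are never guessed. Palindromic SNPs (A/T, C/G), whose orientation
cannot be verified at all, are set to missing with a warning rather than
scored. Coordinates are 1-based (VCF convention); missing genotypes are
`./.` in VCF and empty cells in the CSV matrix format.

## The stratified analysis

`assign_tertiles()` cuts the empirical GRS distribution at its 1/3 and 2/3
quantiles (R's default type-7 quantiles; conventions differ across software,
so the rule is fixed and documented): values strictly below the lower cut
are *low*, values in $[q_{1/3}, q_{2/3})$ are *intermediate*, values at or
above the upper cut are *high*, and ties share a stratum. A degenerate
distribution whose cut points coincide is flagged.

`fit_stratum_bmi_or()` fits, within one stratum, a maximum-likelihood
logistic regression of the biopsy outcome on BMI plus adjustment covariates
and reports the per-unit (kg/m²) BMI odds ratio with Wald 95% CI and
p-value. `fit_interaction()` fits a single pooled model

$$\mathrm{logit}\,P(\text{outcome}) = \beta_0 + \beta_B \,\mathrm{BMI}
 + \gamma_s + \delta_s\,\mathrm{BMI} + \boldsymbol\beta^\top \mathbf{x},$$

with stratum dummies $\gamma_s$ and product terms $\delta_s$ (low stratum as
reference). $e^{\delta_s}$ is the **interaction OR**: the ratio of stratum
$s$'s per-unit BMI odds ratio to the low-stratum one. With no covariates the
pooled model is saturated in stratum, and its per-stratum slopes equal the
stratum-only fits exactly — an identity the test suite checks numerically.

Further analysis decisions:

* The default adjustment set is **age, log-PSA, prostate volume, DRE
  finding, family history** — the conventional biopsy-referral risk factors;
  it is an argument, not a constant.
* CIs and p-values are **Wald-based**, the standard presentation for
  reported logistic ORs, computed with a tightened IRLS convergence
  tolerance (`epsilon = 1e-12`) so algebraic identities hold to ~1e-8.
* **No multiple-testing correction** is applied to the interaction
  p-values; they are reported raw.
* Quasi-separation or non-convergence raises a classed fit error naming the
  stratum instead of returning unstable estimates; a single-class stratum
  raises a degenerate-outcome error.
* The **high-grade** secondary outcome contrasts aggressive disease against
  everyone else (non-high-grade cancers *and* negative biopsies). This
  "high-grade disease risk" definition is a package decision; restricting
  controls to biopsy-negative men is possible by subsetting the cohort
  first.

`baseline_table()` reproduces the conventional cohort-characteristics table:
median (IQR) with Kruskal–Wallis rank tests for continuous variables, count
(%) with chi-squared tests (no continuity correction, so a perfectly
balanced table gives statistic 0 and p = 1) for categorical ones, grouped
either by GRS stratum or by outcome.

## What the synthetic generator emulates

`simulate_cohort()` draws, per subject:

* **Genotypes**: risk-allele counts Binomial(2, $p_i$) — the HWE trinomial —
  independently across SNPs and subjects, with optional uniform missingness.
* **Covariates**: BMI ~ Normal(24, 3) truncated at 15 kg/m² (the typical
  Chinese biopsy-cohort BMI distribution with median near 24); age ~
  Normal(66, 7) truncated at 40; PSA log-normal around 10 ng/mL (biopsy
  referral range); prostate volume ~ Normal(42, 15) truncated at 10 mL;
  Bernoulli comorbidities with prevalences typical of such cohorts (family
  history deliberately rare at 3%).
* **Outcome**: Bernoulli with
  $\mathrm{logit}\,P = \beta_0 + s_{g} + \beta_{B,g}\,(\mathrm{BMI} - \bar B)
  + \sum_j \beta_j \tilde x_j$, where $g$ is the subject's **realized** GRS
  tertile.

Three generator choices deserve explanation:

* **Slopes attach to the realized tertile**, computed by the pipeline's own
  `compute_grs()` + `assign_tertiles()`, not to a latent label. Recovery
  tests therefore exercise the estimator's own stratification and are not
  optimistically biased by an oracle stratum assignment.
* **Continuous predictors are centered** at their configured means and each
  stratum gets an additive intercept shift (`stratum_logit_shift`, default
  ±0.34). With raw BMI near 24 kg/m², a stratum-varying slope would
  otherwise force absurd prevalence gaps between strata; centering keeps
  `baseline_logit` interpretable as the reference log-odds and the shifts
  reproduce the rising positive-biopsy fraction across strata (~36% to ~50%
  at defaults) seen in referral cohorts. The interaction estimand
  $e^{\beta_{B,\text{high}} - \beta_{B,\text{low}}}$ is unchanged by either
  choice.
* **`baseline_logit = -0.53`** was calibrated once, at large n, so the
  default configuration yields an overall positive-biopsy fraction of about
  43.4% — the operating point of the Chinese referral cohorts this design
  emulates. The default BMI slopes (0, 0.08, 0.155 per kg/m² across strata)
  put the high-stratum per-unit BMI OR near 1.17 and the low stratum at
  null, the neighborhood reported for such cohorts; they are defaults, not
  asserted ground truth.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium between panel SNPs
(the score itself assumes multiplicative independence), PSA-driven biopsy
selection and verification bias, population stratification, measurement
error in questionnaire covariates, and repeated-biopsy subjects (the
generator produces one record per subject). Recovery of a simulated
interaction OR shows the estimator is consistent and calibrated under its
own assumptions, not that any particular clinical estimate is correct.

## Problem sizes and numerical tolerances

The replicate studies are sized for repeatable desk-scale runs: type-I
calibration uses 500 replicates of n = 2000 (3·SE acceptance band around
the nominal 0.05); parameter recovery uses 200 replicates of n = 5000
against a simulated high-vs-low interaction OR of 1.2 (mean within 2%,
CI coverage within a 3·SE binomial band of 95%). Exact-arithmetic checks
(HWE frequencies, relative-risk normalization, brute-force GRS enumeration
on panels of ≤ 3 SNPs) use a 1e-12 tolerance in log space. Tertile tie
handling, orientation invariance, and byte-identical re-runs of the
pipeline are asserted exactly.

## Bundled panels

The panels under `inst/extdata/` (`panel_synthetic_24.csv` and its first-7
subset `panel_synthetic_east_asian_7.csv`) are **synthetic stand-ins**:
rsIDs, positions, ORs (log-uniform in [1.05, 1.45]) and frequencies
(uniform in [0.1, 0.9]) are generated by `synthetic_panel()` with a fixed
seed, with non-palindromic allele pairs so VCF round-trips are unambiguous.
They mirror the overall-panel / population-specific-subset pairing used in
practice but carry no published SNP weights.

## Limitations

* The tertile boundaries are estimated from the analyzed cohort, so the
  "low/intermediate/high" labels are cohort-relative, not absolute.
* Wald inference can misbehave in small strata with rare outcomes; the
  package raises errors on separation rather than switching to penalized
  or profile-likelihood methods.
* The continuous BMI × log-GRS formulation is not implemented as a separate
  estimator; the stratified parameterization is the primary contract, and
  `log_grs` is exposed so users can fit the continuous variant directly
  with `stats::glm()`.
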