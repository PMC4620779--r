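# grsbmi

Does body-mass index predict prostate cancer at biopsy equally for everyone,
or mainly for men who already carry high inherited risk? `grsbmi` implements
the analysis needed to ask that question in a biopsy cohort: a
population-standardized multiplicative genetic risk score (GRS), GRS-tertile
risk strata, and stratified / interaction logistic models of BMI on biopsy
outcome — plus a synthetic cohort generator so the whole pipeline runs and is
tested without any clinical data.

It is aimed at biostatisticians and genetic epidemiologists working with
case-control or referral biopsy cohorts genotyped on a SNP risk panel.

## The score and the model

For SNP *i* with allelic odds ratio OR<sub>i</sub> (from an external
association study) and risk-allele frequency p<sub>i</sub>, the
multiplicative model gives genotypic ORs (1, OR<sub>i</sub>,
OR<sub>i</sub>²); Hardy–Weinberg equilibrium gives genotype frequencies
((1−p<sub>i</sub>)², 2p<sub>i</sub>(1−p<sub>i</sub>), p<sub>i</sub>²); each
genotype's risk is divided by the population-average risk
r̄<sub>i</sub> = Σ<sub>g</sub> OR<sub>i</sub><sup>g</sup> f<sub>i,g</sub>,
so every SNP's expected relative risk is exactly 1. A subject's GRS is the
product of their per-SNP relative risks (mean ≈ 1 in the population).

Subjects are stratified at the empirical GRS tertiles. Within stratum *s*,
logistic regression gives the adjusted per-unit BMI odds ratio; a pooled
model with BMI × stratum product terms,

    logit P(outcome) = β0 + βB·BMI + γs + δs·BMI + covariates,

tests effect modification: exp(δs) is the interaction OR of stratum *s*
versus the low-GRS reference.

## Worked example

The numbered scripts under `analysis/` run the full study on a simulated
cohort. `analysis/01_simulate.R` draws 1120 men on the bundled synthetic
24-SNP panel and prints:

```
simulated 1120 subjects; 480 (42.86%) biopsy-positive
median BMI 24.1 kg/m2, median PSA 9.7 ng/mL
```

`analysis/02_score.R` scores the cohort with the 24-SNP panel and its
7-SNP population-specific subset (`mean GRS 1.028`, as expected for a score
standardized to population mean 1), and `analysis/03_interaction.R` runs
the stratified analysis end to end:

```
panel panel_overall24 (24 SNPs): 42.86% biopsy-positive
  low          n= 373  BMI OR 0.965 (0.887-1.050)  P=0.405
  intermediate n= 373  BMI OR 1.133 (1.051-1.221)  P=0.00116
  high         n= 374  BMI OR 1.129 (1.046-1.219)  P=0.00191
  interaction intermediate vs low: OR 1.175  P=0.00452
  interaction high vs low: OR 1.168  P=0.00663
```

Read: in this simulated cohort BMI carries no signal in the low-genetic-risk
stratum (OR 0.965, P = 0.41) but raises the odds of a positive biopsy by
~13% per kg/m² in the intermediate and high strata; the product-term test
confirms the BMI effect differs from the low stratum (interaction OR 1.17,
P < 0.01) — the cohort was simulated with exactly this structure
(per-stratum BMI log-odds slopes 0, 0.08, 0.155). Full tables land in
`results/main/` (`summary.md`, `results.json`, baseline tables).
`analysis/04_operating_characteristics.R` replicates the pipeline to check
the interaction test's size and coverage.

The same machinery is available programmatically:

```r
library(grsbmi)
panel  <- bundled_panel("overall-24")
sim    <- simulate_cohort(sim_config(n_subjects = 1120, panel = panel, seed = 1))
cohort <- build_cohort(sim$grs, sim$phenotypes)
fit_all_strata(cohort)      # per-stratum adjusted BMI ORs
fit_interaction(cohort)     # interaction ORs vs the low-GRS stratum
```

and on real files via `read_panel()`, `read_genotypes_vcf()` /
`read_genotype_matrix()`, `read_phenotypes()` and `run_pipeline()`.

The bundled panels are clearly labelled synthetic stand-ins (generated
weights, not published SNPs); supply your own panel CSV
(`rsid,chrom,pos,risk_allele,other_allele,allelic_or,risk_allele_freq`) for
a real analysis.

## Package layout

- `R/` — panel/genotype/phenotype I/O, the GRS engine, tertile
  stratification and logistic modelling, the synthetic cohort generator,
  and the pipeline runner.
- `analysis/` — the numbered narrative drivers described above.
- `inst/extdata/` — synthetic stand-in panels.
- `vignettes/grs-bmi-interaction.Rmd` — the methods vignette: model,
  assumptions, generator design, numerical choices, limitations.
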