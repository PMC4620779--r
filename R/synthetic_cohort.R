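#' Synthetic biopsy-cohort generator
#'
#' Generates cohorts carrying exactly the statistical structure the analysis
#' assumes: genotypes in Hardy-Weinberg equilibrium at the panel's stated
#' risk-allele frequencies, log-normal PSA, realistic BMI, age and prostate
#' volume, Bernoulli comorbidities, and a logistic biopsy outcome whose
#' per-unit BMI log-odds slope differs by the subject's realized GRS tertile.
#' Because the stratum-specific slopes are applied to the tertile the
#' pipeline itself computes (not to a latent label), recovery tests exercise
#' the estimator's own stratification. SNPs are simulated independently (no
#' linkage disequilibrium).
#'
#' @name synthetic_cohort
NULL

#' Generate a synthetic SNP panel
#'
#' Allelic ORs are log-uniform in `[1.05, 1.45]` and risk-allele frequencies
#' uniform in `[0.1, 0.9]`, typical of confirmed common risk variants. Allele
#' pairs are never palindromic (no A/T or C/G), so panels survive VCF
#' round-trips without strand ambiguity.
#'
#' @param n_snps number of SNPs
#' @param seed RNG seed (the bundled panels were generated with the default)
#' @param name panel name
#' @return a [snp_panel()]
#' @export
synthetic_panel <- function(n_snps = 24, seed = 20150923,
                            name = sprintf("synthetic-%d", n_snps)) {
  stopifnot(n_snps >= 1)
  set.seed(seed)
  pairs <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
  picked <- sample(length(pairs), n_snps, replace = TRUE)
  alleles <- do.call(rbind, pairs[picked])
  snp_panel(data.frame(
    rsid = sprintf("rs9%06d", sample.int(999999, n_snps)),
    chrom = as.character(sample.int(22, n_snps, replace = TRUE)),
    pos = sort(sample.int(5e7, n_snps)),
    risk_allele = alleles[, 1],
    other_allele = alleles[, 2],
    allelic_or = exp(stats::runif(n_snps, log(1.05), log(1.45))),
    risk_allele_freq = stats::runif(n_snps, 0.1, 0.9),
    stringsAsFactors = FALSE
  ), name = name)
}

#' Bundled synthetic stand-in panels
#'
#' Loads the packaged synthetic 24-SNP panel, or its first-7-SNP subset that
#' plays the role of an East-Asian-specific panel, from `inst/extdata`.
#' These are synthetic stand-ins: rsIDs, positions and weights are generated,
#' not taken from any published association study.
#'
#' @param which `"overall-24"` or `"east-asian-7"`
#' @return a [snp_panel()]
#' @export
bundled_panel <- function(which = c("overall-24", "east-asian-7")) {
  which <- match.arg(which)
  file <- switch(which,
                 "overall-24" = "panel_synthetic_24.csv",
                 "east-asian-7" = "panel_synthetic_east_asian_7.csv")
  read_panel(system.file("extdata", file, package = "grsbmi",
                         mustWork = TRUE),
             name = which)
}

#' Simulation configuration
#'
#' Defaults emulate a Chinese tertiary-center prostate biopsy cohort: 1120
#' men, median BMI near 24 kg/m^2, PSA log-normal around 10 ng/mL (biopsy
#' referral range), and an overall positive-biopsy fraction near 43%, with
#' prevalence rising across GRS tertiles. `beta_bmi_by_stratum` holds the
#' per-unit BMI log-odds slope in the low / intermediate / high stratum; the
#' default gives a null BMI effect at low genetic risk growing to a per-unit
#' OR of about 1.17 at high risk. Continuous predictors enter the outcome
#' model centered at their configured means, so `baseline_logit` is the
#' log-odds of a positive biopsy for an average subject in the intermediate
#' stratum and `stratum_logit_shift` sets the prevalence gradient across
#' strata.
#'
#' @param n_subjects cohort size
#' @param panel a [snp_panel()]; default the bundled synthetic 24-SNP panel
#' @param seed RNG seed (mandatory for reproducibility)
#' @param bmi_mean,bmi_sd BMI distribution, kg/m^2 (truncated at 15)
#' @param age_mean,age_sd age distribution, years (truncated at 40)
#' @param log_psa_mean,log_psa_sd log-PSA distribution (PSA in ng/mL)
#' @param volume_mean,volume_sd prostate volume, mL (truncated at 10)
#' @param prevalences named list of Bernoulli prevalences for the binary
#'   covariates
#' @param baseline_logit reference log-odds of a positive biopsy
#' @param stratum_logit_shift additive log-odds shift per stratum
#' @param beta_bmi_by_stratum per-unit BMI log-OR per stratum
#'   (low, intermediate, high)
#' @param beta_covariates named log-OR per covariate (continuous ones are
#'   centered at their configured means)
#' @param p_high_grade probability a positive biopsy is high-grade
#' @param missing_rate genotype missingness rate in `[0, 1)`
#' @return validated `sim_config` list
#' @export
sim_config <- function(n_subjects = 1120,
                       panel = bundled_panel("overall-24"),
                       seed = 1,
                       bmi_mean = 24, bmi_sd = 3,
                       age_mean = 66, age_sd = 7,
                       log_psa_mean = log(10), log_psa_sd = 0.9,
                       volume_mean = 42, volume_sd = 15,
                       prevalences = list(dre_abnormal = 0.25,
                                          family_history = 0.03,
                                          smoking = 0.45,
                                          drinking = 0.30,
                                          hypertension = 0.30,
                                          diabetes = 0.12),
                       baseline_logit = -0.53,
                       stratum_logit_shift = c(low = -0.34,
                                               intermediate = 0,
                                               high = 0.34),
                       beta_bmi_by_stratum = c(low = 0,
                                               intermediate = 0.08,
                                               high = 0.155),
                       beta_covariates = c(age = 0.03,
                                           log_psa = 0.9,
                                           prostate_volume = -0.015,
                                           dre_abnormal = 0.8,
                                           family_history = 0.7),
                       p_high_grade = 0.4,
                       missing_rate = 0) {
  cfg <- list(n_subjects = as.integer(n_subjects), panel = panel,
              seed = as.integer(seed),
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              age_mean = age_mean, age_sd = age_sd,
              log_psa_mean = log_psa_mean, log_psa_sd = log_psa_sd,
              volume_mean = volume_mean, volume_sd = volume_sd,
              prevalences = prevalences,
              baseline_logit = baseline_logit,
              stratum_logit_shift = stratum_logit_shift,
              beta_bmi_by_stratum = beta_bmi_by_stratum,
              beta_covariates = beta_covariates,
              p_high_grade = p_high_grade,
              missing_rate = missing_rate)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!inherits(cfg$panel, "snp_panel")) {
    stop_grsbmi("sim_config: panel must be a snp_panel", "grsbmi_config_error")
  }
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 1) {
    stop_grsbmi("sim_config: n_subjects must be >= 1", "grsbmi_config_error")
  }
  sds <- c(cfg$bmi_sd, cfg$age_sd, cfg$log_psa_sd, cfg$volume_sd)
  if (any(!is.finite(sds) | sds <= 0)) {
    stop_grsbmi("sim_config: all sd parameters must be > 0",
                "grsbmi_config_error")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop_grsbmi("sim_config: missing_rate must lie in [0, 1)",
                "grsbmi_config_error")
  }
  if (length(cfg$beta_bmi_by_stratum) != 3) {
    stop_grsbmi("sim_config: beta_bmi_by_stratum must have 3 entries (low, intermediate, high)",
                "grsbmi_config_error")
  }
  needed <- c("dre_abnormal", "family_history", "smoking", "drinking",
              "hypertension", "diabetes")
  if (!all(needed %in% names(cfg$prevalences))) {
    stop_grsbmi(sprintf("sim_config: prevalences must name all of: %s",
                        paste(needed, collapse = ", ")),
                "grsbmi_config_error")
  }
  prev <- unlist(cfg$prevalences)
  if (any(prev < 0 | prev > 1)) {
    stop_grsbmi("sim_config: prevalences must lie in [0, 1]",
                "grsbmi_config_error")
  }
  if (cfg$p_high_grade < 0 || cfg$p_high_grade > 1) {
    stop_grsbmi("sim_config: p_high_grade must lie in [0, 1]",
                "grsbmi_config_error")
  }
  structure(cfg, class = "sim_config")
}

# genotype draw without touching the seed (callers set it)
sim_genotypes_impl <- function(cfg) {
  n <- cfg$n_subjects
  panel <- cfg$panel
  m <- vapply(panel$risk_allele_freq,
              function(p) stats::rbinom(n, 2, p),
              integer(n))
  dim(m) <- c(n, nrow(panel))
  if (cfg$missing_rate > 0) {
    m[stats::runif(length(m)) < cfg$missing_rate] <- NA_integer_
  }
  dimnames(m) <- list(sprintf("S%05d", seq_len(n)), panel$rsid)
  storage.mode(m) <- "integer"
  m
}

#' Simulate HWE genotypes
#'
#' Per SNP, risk-allele counts are drawn Binomial(2, p) — the Hardy-Weinberg
#' trinomial at the panel's risk-allele frequency — independently across SNPs
#' and subjects. Missing entries are injected uniformly at random at
#' `missing_rate`. Reproducible for a fixed `seed`.
#'
#' @param config a [sim_config()]
#' @return integer matrix of risk-allele counts (subjects x panel SNPs)
#' @export
simulate_genotypes <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  sim_genotypes_impl(config)
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a full biopsy cohort
#'
#' Draws genotypes, scores them with [compute_grs()], assigns GRS tertiles
#' with [assign_tertiles()], draws covariates, and generates the biopsy
#' outcome from `Bernoulli(plogis(eta))` with
#' `eta = baseline_logit + stratum_logit_shift[s] +
#' beta_bmi_by_stratum[s] * (bmi - bmi_mean) + sum beta_j * x_j` (continuous
#' covariates centered at their configured means). High-grade disease is
#' drawn among cases with probability `p_high_grade`.
#'
#' @param config a [sim_config()]
#' @return list with `genotypes` (integer matrix), `phenotypes` (validated
#'   phenotype data.frame) and `grs` (the [compute_grs()] result used to
#'   assign strata)
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  genotypes <- sim_genotypes_impl(cfg)
  grs <- suppressWarnings(compute_grs(genotypes, cfg$panel,
                                      missing_policy = "neutral"))
  # keep the triple consistent if any all-missing subject was excluded
  genotypes <- genotypes[grs$subject_id, , drop = FALSE]
  n <- nrow(grs)
  stratum <- assign_tertiles(grs$grs)

  prev <- cfg$prevalences
  ph <- data.frame(
    subject_id = grs$subject_id,
    age = rnorm_trunc(n, cfg$age_mean, cfg$age_sd, 40),
    bmi = rnorm_trunc(n, cfg$bmi_mean, cfg$bmi_sd, 15),
    psa = exp(stats::rnorm(n, cfg$log_psa_mean, cfg$log_psa_sd)),
    prostate_volume = rnorm_trunc(n, cfg$volume_mean, cfg$volume_sd, 10),
    dre_abnormal = stats::runif(n) < prev$dre_abnormal,
    family_history = stats::runif(n) < prev$family_history,
    smoking = stats::runif(n) < prev$smoking,
    drinking = stats::runif(n) < prev$drinking,
    hypertension = stats::runif(n) < prev$hypertension,
    diabetes = stats::runif(n) < prev$diabetes,
    stringsAsFactors = FALSE
  )

  centers <- c(age = cfg$age_mean, log_psa = cfg$log_psa_mean,
               prostate_volume = cfg$volume_mean)
  eta <- cfg$baseline_logit +
    unname(cfg$stratum_logit_shift[as.integer(stratum)]) +
    unname(cfg$beta_bmi_by_stratum[as.integer(stratum)]) *
      (ph$bmi - cfg$bmi_mean)
  for (term in names(cfg$beta_covariates)) {
    x <- if (term == "log_psa") log(ph$psa) else ph[[term]]
    if (term %in% names(centers)) x <- x - centers[[term]]
    eta <- eta + cfg$beta_covariates[[term]] * as.numeric(x)
  }
  ph$pca <- stats::runif(n) < stats::plogis(eta)
  case_fraction <- mean(ph$pca)
  if (case_fraction == 0 || case_fraction == 1) {
    warn_grsbmi(sprintf("degenerate outcome: observed case fraction is %.3f (check baseline_logit)",
                        case_fraction),
                "grsbmi_degenerate_outcome_sim")
  }
  ph$high_grade <- ph$pca & stats::runif(n) < cfg$p_high_grade

  list(genotypes = genotypes, phenotypes = validate_phenotypes(ph), grs = grs)
}

#' Write a simulated cohort to disk
#'
#' Emits files readable by the package's own readers without information
#' loss: `phenotypes.csv` plus either `genotypes.csv` (risk-allele-count
#' matrix) or `genotypes.vcf` (VCF 4.2, GT field, REF = other allele, ALT =
#' risk allele).
#'
#' @param genotypes integer risk-allele-count matrix
#' @param phenotypes validated phenotype table
#' @param out_dir output directory (created if needed)
#' @param format `"csv"` or `"vcf+csv"`
#' @param panel the `snp_panel`; required for `"vcf+csv"`
#' @return named character vector of file paths, invisibly
#' @export
write_cohort <- function(genotypes, phenotypes, out_dir,
                         format = c("csv", "vcf+csv"), panel = NULL) {
  format <- match.arg(format)
  if (!setequal(rownames(genotypes), phenotypes$subject_id)) {
    stop_grsbmi("genotype and phenotype subject IDs do not match",
                "grsbmi_validation_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pheno_path <- file.path(out_dir, "phenotypes.csv")
  write_phenotypes(phenotypes, pheno_path)
  if (format == "csv") {
    geno_path <- file.path(out_dir, "genotypes.csv")
    write_genotype_matrix(genotypes, geno_path)
  } else {
    if (is.null(panel)) {
      stop_grsbmi("panel is required to write VCF output",
                  "grsbmi_config_error")
    }
    geno_path <- file.path(out_dir, "genotypes.vcf")
    write_genotypes_vcf(genotypes, panel, geno_path)
  }
  invisible(c(genotypes = geno_path, phenotypes = pheno_path))
}

#' Write a risk-allele-count matrix as a VCF
#'
#' Minimal VCF 4.2 with the GT FORMAT field only. ALT is the panel's risk
#' allele, so the emitted ALT dosage equals the risk-allele count; missing
#' counts become `./.`.
#'
#' @param genotypes integer matrix (subjects x panel rsids)
#' @param panel the `snp_panel`
#' @param path output `.vcf` path
#' @return `path`, invisibly
#' @export
write_genotypes_vcf <- function(genotypes, panel, path) {
  genotypes <- as_genotype_matrix(genotypes, panel)
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=grsbmi_synthetic_cohort",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(panel)), function(j) {
    counts <- genotypes[, j]
    gts <- ifelse(is.na(counts), "./.", gt_codes[counts + 1L])
    paste(c(panel$chrom[j], panel$pos[j], panel$rsid[j],
            panel$other_allele[j], panel$risk_allele[j],
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
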