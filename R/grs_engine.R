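#' Population-standardized multiplicative genetic risk score
#'
#' The score is built in four steps. (1) Each SNP carries an allelic odds
#' ratio from an external association study. (2) Genotypic odds ratios follow
#' the multiplicative model: 1, OR, OR^2 for 0, 1, 2 copies of the risk
#' allele. (3) Each genotype's risk is expressed relative to the average risk
#' in the reference population, obtained by weighting the genotypic ORs with
#' Hardy-Weinberg genotype frequencies at the stated risk-allele frequency;
#' the population-expected relative risk of every SNP is therefore exactly 1.
#' (4) A subject's GRS is the product of their per-SNP relative risks, so the
#' score has population mean approximately 1 and values above 1 mark
#' above-average inherited risk.
#'
#' @name grs_engine
NULL

#' Genotypic odds ratios under the multiplicative model
#'
#' @param allelic_or odds ratio per copy of the risk allele (> 0)
#' @return numeric vector `c(1, allelic_or, allelic_or^2)`, indexed by
#'   risk-allele count 0, 1, 2.
#' @examples
#' genotypic_or(1.5)  # c(1, 1.5, 2.25)
#' @export
genotypic_or <- function(allelic_or) {
  if (!is.numeric(allelic_or) || length(allelic_or) != 1 ||
      !is.finite(allelic_or) || allelic_or <= 0) {
    stop_grsbmi("allelic_or must be a single positive number",
                "grsbmi_domain_error")
  }
  c(1, allelic_or, allelic_or^2)
}

#' Hardy-Weinberg genotype frequencies
#'
#' @param p risk-allele frequency, strictly inside (0, 1)
#' @return numeric vector `c((1-p)^2, 2p(1-p), p^2)`, indexed by risk-allele
#'   count 0, 1, 2; sums to 1.
#' @examples
#' hwe_genotype_freqs(0.3)  # c(0.49, 0.42, 0.09)
#' @export
hwe_genotype_freqs <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p <= 0 || p >= 1) {
    stop_grsbmi("risk-allele frequency must lie strictly in (0, 1)",
                "grsbmi_domain_error")
  }
  c((1 - p)^2, 2 * p * (1 - p), p^2)
}

#' Per-SNP risk relative to the population average
#'
#' Combines the multiplicative genotypic ORs with HWE genotype frequencies to
#' express each genotype's risk relative to the population-average risk.
#' By construction `sum(relative_risk * genotype_freq) == 1`.
#'
#' @param snp one panel row (or any list) with fields `allelic_or` and
#'   `risk_allele_freq`; an `rsid` field is carried through if present.
#' @return list with `rsid`, `genotypic_or`, `genotype_freq`, `mean_risk`
#'   and `relative_risk` (all genotype-indexed by risk-allele count 0, 1, 2).
#' @examples
#' prof <- snp_risk_profile(list(allelic_or = 1.5, risk_allele_freq = 0.3))
#' prof$mean_risk       # 1.3225
#' prof$relative_risk   # c(0.7561437, 1.1342155, 1.7013233)
#' @export
snp_risk_profile <- function(snp) {
  g_or <- genotypic_or(snp$allelic_or)
  freq <- hwe_genotype_freqs(snp$risk_allele_freq)
  mean_risk <- sum(g_or * freq)
  list(
    rsid = if (!is.null(snp$rsid)) as.character(snp$rsid) else NA_character_,
    genotypic_or = g_or,
    genotype_freq = freq,
    mean_risk = mean_risk,
    relative_risk = g_or / mean_risk
  )
}

# 3 x k matrix of log relative risks, rows indexed by risk-allele count 0..2.
panel_log_relative_risk <- function(panel) {
  vapply(seq_len(nrow(panel)),
         function(j) log(snp_risk_profile(panel[j, ])$relative_risk),
         numeric(3))
}

#' Compute per-subject genetic risk scores
#'
#' GRS is the product over panel SNPs of each subject's genotype risk relative
#' to the population average. Products are accumulated in log space so large
#' panels cannot underflow. Under `missing_policy = "neutral"` a missing
#' genotype contributes the neutral factor 1 (the population-average risk);
#' under `"drop_subject"` any missingness excludes the subject. Subjects with
#' no usable genotype at all are excluded with a warning in either policy.
#'
#' @param genotypes integer matrix of risk-allele counts
#'   (subjects x rsids, NA = missing), e.g. from [read_genotypes_vcf()] or
#'   [simulate_genotypes()].
#' @param panel a [snp_panel()] covering the matrix columns
#' @param missing_policy `"neutral"` (default) or `"drop_subject"`
#' @return data.frame with columns `subject_id`, `grs`, `log_grs`,
#'   `n_snps_used`, `n_snps_missing`; one row per retained subject.
#' @export
compute_grs <- function(genotypes, panel,
                        missing_policy = c("neutral", "drop_subject")) {
  missing_policy <- match.arg(missing_policy)
  genotypes <- as_genotype_matrix(genotypes, panel)
  k <- nrow(panel)
  log_rr <- panel_log_relative_risk(panel)

  n_missing <- rowSums(is.na(genotypes))
  log_grs <- numeric(nrow(genotypes))
  for (j in seq_len(k)) {
    contrib <- log_rr[genotypes[, j] + 1L, j]
    contrib[is.na(contrib)] <- 0  # neutral factor: population-average risk
    log_grs <- log_grs + contrib
  }

  keep <- if (missing_policy == "drop_subject") n_missing == 0 else n_missing < k
  dropped <- rownames(genotypes)[!keep]
  if (length(dropped) > 0) {
    reason <- if (missing_policy == "drop_subject") {
      "missing genotypes under drop_subject policy"
    } else {
      "all genotypes missing"
    }
    warn_grsbmi(sprintf("excluded %d subject(s) (%s): %s",
                        length(dropped), reason,
                        paste(utils::head(dropped, 10), collapse = ", ")),
                "grsbmi_subjects_excluded")
  }

  data.frame(
    subject_id = rownames(genotypes)[keep],
    grs = exp(log_grs[keep]),
    log_grs = log_grs[keep],
    n_snps_used = as.integer(k - n_missing[keep]),
    n_snps_missing = as.integer(n_missing[keep]),
    stringsAsFactors = FALSE
  )
}

#' Log-transformed GRS accessor
#'
#' The multiplicative score is right-skewed; diagnostics and regression
#' adjustments conventionally use its natural logarithm.
#'
#' @param x a [compute_grs()] result or a numeric GRS vector
#' @return numeric vector of log-GRS values
#' @export
log_grs <- function(x) {
  if (is.data.frame(x)) {
    if (!is.null(x$log_grs)) return(x$log_grs)
    return(log(x$grs))
  }
  log(x)
}
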