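#' SNP panel, genotype, and phenotype input/output
#'
#' A SNP panel is the weight table of the risk score: one row per SNP with its
#' risk allele, the allelic odds ratio taken from an external association
#' study, and the risk-allele frequency in the reference population. Genotypes
#' are per-subject risk-allele counts (0/1/2, NA for missing). Phenotypes carry
#' the clinical covariates and the biopsy outcome.
#'
#' @name panel_io
NULL

PANEL_COLUMNS <- c("rsid", "chrom", "pos", "risk_allele", "other_allele",
                   "allelic_or", "risk_allele_freq")

PHENOTYPE_BOOL_COLUMNS <- c("dre_abnormal", "family_history", "smoking",
                            "drinking", "hypertension", "diabetes",
                            "pca", "high_grade")

PHENOTYPE_COLUMNS <- c("subject_id", "age", "bmi", "psa", "prostate_volume",
                       PHENOTYPE_BOOL_COLUMNS)

#' Construct a validated SNP panel
#'
#' @param snps data.frame with columns rsid, chrom, pos, risk_allele,
#'   other_allele, allelic_or, risk_allele_freq.
#' @param name panel name, e.g. `"overall-24"` or `"east-asian-7"`.
#' @return A `snp_panel`: the validated data.frame with a `name` attribute.
#' @export
snp_panel <- function(snps, name = "panel") {
  missing_cols <- setdiff(PANEL_COLUMNS, names(snps))
  if (length(missing_cols) > 0) {
    stop_grsbmi(
      sprintf("panel is missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "grsbmi_format_error"
    )
  }
  snps <- as.data.frame(snps)[, PANEL_COLUMNS]
  if (nrow(snps) == 0) {
    stop_grsbmi("panel must contain at least one SNP", "grsbmi_validation_error")
  }
  snps$rsid <- as.character(snps$rsid)
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  snps$risk_allele <- toupper(as.character(snps$risk_allele))
  snps$other_allele <- toupper(as.character(snps$other_allele))
  snps$allelic_or <- as.numeric(snps$allelic_or)
  snps$risk_allele_freq <- as.numeric(snps$risk_allele_freq)

  dup <- unique(snps$rsid[duplicated(snps$rsid)])
  if (length(dup) > 0) {
    stop_grsbmi(sprintf("duplicate rsid(s) in panel: %s",
                        paste(dup, collapse = ", ")),
                "grsbmi_validation_error")
  }
  bad_allele <- !(snps$risk_allele %in% c("A", "C", "G", "T")) |
    !(snps$other_allele %in% c("A", "C", "G", "T")) |
    snps$risk_allele == snps$other_allele
  if (any(bad_allele)) {
    stop_grsbmi(sprintf("invalid allele pair for rsid(s): %s",
                        paste(snps$rsid[bad_allele], collapse = ", ")),
                "grsbmi_validation_error")
  }
  bad_or <- !is.finite(snps$allelic_or) | snps$allelic_or <= 0
  if (any(bad_or)) {
    stop_grsbmi(sprintf("allelic_or must be > 0; offending rsid(s): %s",
                        paste(snps$rsid[bad_or], collapse = ", ")),
                "grsbmi_validation_error")
  }
  bad_freq <- !is.finite(snps$risk_allele_freq) |
    snps$risk_allele_freq <= 0 | snps$risk_allele_freq >= 1
  if (any(bad_freq)) {
    stop_grsbmi(sprintf("risk_allele_freq must lie in (0, 1); offending rsid(s): %s",
                        paste(snps$rsid[bad_freq], collapse = ", ")),
                "grsbmi_validation_error")
  }
  rownames(snps) <- NULL
  structure(snps, name = as.character(name),
            class = c("snp_panel", "data.frame"))
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("<snp_panel '%s': %d SNPs>\n", panel_name(x), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Panel name accessor
#' @param panel a `snp_panel`
#' @return the panel's name string
#' @export
panel_name <- function(panel) attr(panel, "name") %||% "panel"

#' Read a SNP panel from CSV
#'
#' Expected columns: `rsid,chrom,pos,risk_allele,other_allele,allelic_or,
#' risk_allele_freq` (header row mandatory, UTF-8). Rows violating the panel
#' invariants (OR <= 0, frequency outside (0,1), duplicate rsid, malformed
#' alleles) raise a validation error naming the offending rsid.
#'
#' @param path CSV file path.
#' @param name panel name; defaults to the file name without extension.
#' @return a [snp_panel()]
#' @export
read_panel <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop_grsbmi(sprintf("panel file not found: %s", path), "grsbmi_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  snp_panel(df, name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a SNP panel to CSV
#' @param panel a `snp_panel`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel)[, PANEL_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Validate a risk-allele-count matrix against a panel; returns an integer
# matrix (subjects x panel SNPs, panel column order).
as_genotype_matrix <- function(counts, panel) {
  counts <- as.matrix(counts)
  missing_rsids <- setdiff(panel$rsid, colnames(counts))
  if (length(missing_rsids) > 0) {
    stop_grsbmi(sprintf("genotype matrix lacks panel rsid(s): %s",
                        paste(missing_rsids, collapse = ", ")),
                "grsbmi_validation_error")
  }
  counts <- counts[, panel$rsid, drop = FALSE]
  storage.mode(counts) <- "integer"
  bad <- !is.na(counts) & !(counts %in% 0:2)
  if (any(bad)) {
    stop_grsbmi("genotype counts must be 0, 1, 2 or missing",
                "grsbmi_validation_error")
  }
  counts
}

#' Read a risk-allele-count matrix from CSV
#'
#' First column `subject_id`; remaining columns one per rsid holding the count
#' of the panel's risk allele (0/1/2), empty cells meaning missing.
#'
#' @param path CSV path
#' @param panel the companion `snp_panel`; every panel rsid must be a column.
#' @return integer matrix, subjects in rows, panel SNPs in columns.
#' @export
read_genotype_matrix <- function(path, panel) {
  if (!file.exists(path)) {
    stop_grsbmi(sprintf("genotype file not found: %s", path), "grsbmi_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(df)) {
    stop_grsbmi("genotype CSV is missing required column: subject_id",
                "grsbmi_format_error")
  }
  m <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  rownames(m) <- as.character(df$subject_id)
  as_genotype_matrix(m, panel)
}

#' Write a risk-allele-count matrix to CSV
#' @param genotypes integer matrix (subjects x rsids), NA = missing
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_genotype_matrix <- function(genotypes, path) {
  df <- data.frame(subject_id = rownames(genotypes),
                   genotypes, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  pair <- paste(sort(c(a1, a2)), collapse = "/")
  pair %in% c("A/T", "C/G")
}

#' Read panel genotypes from a VCF
#'
#' Panel SNPs are located by rsid in the VCF ID column, falling back to
#' CHROM+POS. At each located site the per-subject count of the panel's risk
#' allele is derived from the GT field: if ALT is the risk allele the ALT
#' dosage is used directly; if REF is the risk allele the count is complemented
#' (2 - ALT dosage). A site whose REF/ALT pair does not match the panel's
#' allele pair raises an allele-mismatch error naming the rsid; strand flips
#' are never inferred. Palindromic panel SNPs (A/T or C/G) are set to missing
#' with a warning because their orientation cannot be verified against a
#' strand flip. Panel SNPs absent from the VCF are missing for all subjects.
#'
#' @param path VCF 4.x file (GT field required)
#' @param panel the `snp_panel` to score against
#' @return integer matrix, subjects in rows, panel SNPs in columns.
#' @export
read_genotypes_vcf <- function(path, panel) {
  if (!file.exists(path)) {
    stop_grsbmi(sprintf("VCF file not found: %s", path), "grsbmi_io_error")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  subjects <- colnames(gt)
  out <- matrix(NA_integer_, nrow = length(subjects), ncol = nrow(panel),
                dimnames = list(subjects, panel$rsid))

  for (j in seq_len(nrow(panel))) {
    snp <- panel[j, ]
    if (is_palindromic(snp$risk_allele, snp$other_allele)) {
      warn_grsbmi(
        sprintf("rsid %s is strand-ambiguous (%s/%s); genotypes set to missing",
                snp$rsid, snp$risk_allele, snp$other_allele),
        "grsbmi_ambiguous_strand"
      )
      next
    }
    idx <- which(fix[, "ID"] == snp$rsid)
    if (length(idx) == 0) {
      idx <- which(fix[, "CHROM"] == snp$chrom &
                     as.integer(fix[, "POS"]) == snp$pos)
    }
    if (length(idx) == 0) {
      warn_grsbmi(sprintf("rsid %s not found in VCF; missing for all subjects",
                          snp$rsid),
                  "grsbmi_site_missing")
      next
    }
    idx <- idx[1]
    ref <- toupper(fix[idx, "REF"])
    alt <- toupper(fix[idx, "ALT"])
    alt_dosage <- gt_to_alt_dosage(gt[idx, ])
    if (ref == snp$other_allele && alt == snp$risk_allele) {
      out[, j] <- alt_dosage
    } else if (ref == snp$risk_allele && alt == snp$other_allele) {
      out[, j] <- 2L - alt_dosage
    } else {
      stop_grsbmi(
        sprintf("rsid %s: VCF alleles %s/%s match neither orientation of panel alleles %s/%s",
                snp$rsid, ref, alt, snp$risk_allele, snp$other_allele),
        "grsbmi_allele_mismatch"
      )
    }
  }
  out
}

# "0/1", "1|1", "./." -> ALT allele dosage (NA for any missing allele)
gt_to_alt_dosage <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0 || any(a == "." | is.na(a))) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
}

#' Read a phenotype/covariate table from CSV
#'
#' Required columns: `subject_id, age, bmi, psa, prostate_volume,
#' dre_abnormal, family_history, smoking, drinking, hypertension, diabetes,
#' pca, high_grade`. Boolean columns accept 0/1, yes/no, true/false
#' case-insensitively. `pca` is the biopsy outcome (prostate cancer found);
#' `high_grade` flags aggressive disease and may only be TRUE when `pca` is.
#'
#' @param path CSV path
#' @return validated data.frame, one row per subject
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) {
    stop_grsbmi(sprintf("phenotype file not found: %s", path), "grsbmi_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PHENOTYPE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop_grsbmi(sprintf("phenotype table is missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")),
                "grsbmi_format_error")
  }
  validate_phenotypes(df)
}

#' @rdname read_phenotypes
#' @param df a raw phenotype data.frame to validate in place of a file
#' @export
validate_phenotypes <- function(df) {
  df <- as.data.frame(df)
  df$subject_id <- as.character(df$subject_id)
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup) > 0) {
    stop_grsbmi(sprintf("duplicate subject_id(s): %s",
                        paste(dup, collapse = ", ")),
                "grsbmi_validation_error")
  }
  for (col in c("age", "bmi", "psa", "prostate_volume")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in PHENOTYPE_BOOL_COLUMNS) {
    df[[col]] <- parse_bool(df[[col]], col, df$subject_id)
  }
  bad_bmi <- !is.na(df$bmi) & df$bmi <= 0
  bad_psa <- !is.na(df$psa) & df$psa <= 0
  bad_vol <- !is.na(df$prostate_volume) & df$prostate_volume <= 0
  if (any(bad_bmi | bad_psa | bad_vol)) {
    stop_grsbmi(
      sprintf("bmi, psa and prostate_volume must be > 0; offending subject(s): %s",
              paste(df$subject_id[bad_bmi | bad_psa | bad_vol], collapse = ", ")),
      "grsbmi_validation_error"
    )
  }
  inconsistent <- !is.na(df$high_grade) & df$high_grade &
    (is.na(df$pca) | !df$pca)
  if (any(inconsistent)) {
    stop_grsbmi(
      sprintf("high_grade is TRUE while pca is not for subject(s): %s",
              paste(df$subject_id[inconsistent], collapse = ", ")),
      "grsbmi_consistency_error"
    )
  }
  rownames(df) <- NULL
  df
}

#' Write a phenotype table to CSV
#' @param phenotypes validated phenotype data.frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_phenotypes <- function(phenotypes, path) {
  out <- phenotypes
  for (col in intersect(PHENOTYPE_BOOL_COLUMNS, names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
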