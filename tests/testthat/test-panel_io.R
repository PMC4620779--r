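test_that("read_panel reads a valid panel and preserves every field", {
  p <- tiny_panel(ors = runif(7, 1.05, 1.45), freqs = runif(7, 0.1, 0.9),
                  name = "east-asian-7")
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, path)
  back <- read_panel(path, name = "east-asian-7")
  expect_s3_class(back, "snp_panel")
  expect_equal(nrow(back), 7)
  expect_equal(panel_name(back), "east-asian-7")
  expect_equal(as.data.frame(back), as.data.frame(p))
})

test_that("read_panel rejects invariant violations, naming the culprit", {
  p <- as.data.frame(tiny_panel())
  path <- withr::local_tempfile(fileext = ".csv")

  bad_or <- p; bad_or$allelic_or[2] <- 0
  write.csv(bad_or, path, row.names = FALSE)
  expect_error(read_panel(path), "rs002", class = "grsbmi_validation_error")

  bad_freq <- p; bad_freq$risk_allele_freq[1] <- 1.2
  write.csv(bad_freq, path, row.names = FALSE)
  expect_error(read_panel(path), "rs001", class = "grsbmi_validation_error")

  dup <- rbind(p, p[1, ])
  write.csv(dup, path, row.names = FALSE)
  expect_error(read_panel(path), "rs001", class = "grsbmi_validation_error")

  write.csv(p[, setdiff(names(p), "risk_allele_freq")], path,
            row.names = FALSE)
  expect_error(read_panel(path), "risk_allele_freq",
               class = "grsbmi_format_error")
})

test_that("phenotype reader validates types, positivity and consistency", {
  ph <- make_phenotypes(10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(ph, path)
  back <- read_phenotypes(path)
  expect_equal(nrow(back), 10)
  expect_type(back$pca, "logical")
  expect_equal(back$pca, ph$pca)
  expect_equal(back$bmi, ph$bmi)

  bad <- ph; bad$psa[3] <- -1
  write_phenotypes(bad, path)
  expect_error(read_phenotypes(path), bad$subject_id[3],
               class = "grsbmi_validation_error")

  bad <- ph; bad$pca[2] <- FALSE; bad$high_grade[2] <- TRUE
  write_phenotypes(bad, path)
  expect_error(read_phenotypes(path), "high_grade",
               class = "grsbmi_consistency_error")

  write.csv(ph[, setdiff(names(ph), "bmi")], path, row.names = FALSE)
  expect_error(read_phenotypes(path), "bmi", class = "grsbmi_format_error")
})

test_that("boolean columns accept 0/1, yes/no, true/false case-insensitively", {
  ph <- make_phenotypes(6)
  ph$smoking <- c("Yes", "NO", "true", "False", "1", "0")
  ph$pca <- c(1, 0, 1, 0, 1, 0)
  ph$high_grade <- c("yes", "no", "no", "0", "TRUE", "false")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(ph, path, row.names = FALSE)
  back <- read_phenotypes(path)
  expect_equal(back$smoking, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(back$high_grade, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("genotype CSV matrix round-trips exactly, including missing cells", {
  panel <- tiny_panel(ors = c(1.3, 1.1, 1.4), freqs = c(0.2, 0.5, 0.7))
  m <- counts_matrix(c(0, 1, 2,
                       2, NA, 0,
                       1, 1, NA), panel)
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotype_matrix(m, path)
  back <- read_genotype_matrix(path, panel)
  expect_identical(back, m)
})

test_that("VCF round-trip recovers the simulated genotype matrix exactly", {
  panel <- bundled_panel("east-asian-7")
  cfg <- sim_config(n_subjects = 40, panel = panel, seed = 5,
                    missing_rate = 0.1)
  m <- simulate_genotypes(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(m, panel, path)
  back <- read_genotypes_vcf(path, panel)
  expect_identical(back[rownames(m), colnames(m)], m)
})

test_that("risk-allele counts are orientation-invariant under REF/ALT flips", {
  panel <- tiny_panel(ors = c(1.5, 1.2), freqs = c(0.3, 0.6))
  m <- counts_matrix(c(0, 1,
                       1, 2,
                       2, NA), panel)
  fwd <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(m, panel, fwd)

  # flip orientation: swap REF/ALT and complement the GT codes
  lines <- readLines(fwd)
  is_body <- !startsWith(lines, "#")
  flipped <- vapply(lines[is_body], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[c(4, 5)] <- f[c(5, 4)]
    gts <- f[-(1:9)]
    gts[gts == "0/0"] <- "x"; gts[gts == "1/1"] <- "0/0"; gts[gts == "x"] <- "1/1"
    paste(c(f[1:9], gts), collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  rev <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(lines[!is_body], flipped), rev)

  expect_identical(read_genotypes_vcf(rev, panel),
                   read_genotypes_vcf(fwd, panel))
  # and the complement rule directly: subject 1 carries GT 1/1 in the
  # flipped file, where REF is the risk allele, so the count is 2 - 2 = 0
  expect_identical(unname(read_genotypes_vcf(rev, panel)[1, 1]), 0L)
})

test_that("VCF reader handles absent sites, mismatches, and strand ambiguity", {
  panel <- tiny_panel(ors = c(1.5, 1.2), freqs = c(0.3, 0.6))
  m <- counts_matrix(c(0, 1, 1, 2), panel)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(m, panel, path)

  # a panel SNP absent from the VCF is missing for everyone, with a warning
  extra <- snp_panel(rbind(as.data.frame(panel),
                           data.frame(rsid = "rs999", chrom = "9",
                                      pos = 999L, risk_allele = "A",
                                      other_allele = "C", allelic_or = 1.2,
                                      risk_allele_freq = 0.4)))
  expect_warning(got <- read_genotypes_vcf(path, extra),
                 class = "grsbmi_site_missing")
  expect_true(all(is.na(got[, "rs999"])))
  expect_identical(got[, panel$rsid], m)

  # risk allele matching neither REF nor ALT is an error naming the rsid
  clash <- as.data.frame(panel)
  clash$risk_allele[1] <- "C"; clash$other_allele[1] <- "T"
  expect_error(read_genotypes_vcf(path, snp_panel(clash)), "rs001",
               class = "grsbmi_allele_mismatch")

  # palindromic SNPs are refused (set missing) rather than silently flipped
  pal <- as.data.frame(panel)
  pal$risk_allele[2] <- "C"; pal$other_allele[2] <- "G"
  expect_warning(got2 <- read_genotypes_vcf(path, snp_panel(pal)),
                 class = "grsbmi_ambiguous_strand")
  expect_true(all(is.na(got2[, 2])))
})
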