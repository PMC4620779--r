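#' End-to-end pipeline: score, stratify, analyze, report
#'
#' One reproducible run over files on disk: read the panel(s), genotypes and
#' phenotypes; compute the GRS per panel; assign tertile strata; fit the
#' per-stratum BMI odds ratios, the BMI-by-stratum interaction model, and the
#' baseline characteristics table; write machine-readable results plus a
#' human-readable summary shaped like the stratified-OR/interaction tables of
#' biopsy-cohort reports.
#'
#' @name cli_report
NULL

#' Build a pipeline run configuration
#'
#' @param panel path to the (primary) panel CSV
#' @param genotypes path to genotypes: `.vcf` files go through
#'   [read_genotypes_vcf()], anything else through [read_genotype_matrix()]
#' @param phenotypes path to the phenotype CSV
#' @param out_dir output directory
#' @param outcome `"pca"` or `"high_grade"`
#' @param covariates adjustment terms; default [default_covariates()]
#' @param missing_policy [compute_grs()] missing-genotype policy
#' @param panel2 optional second panel CSV (e.g. a population-specific
#'   subset), analyzed in parallel with the first
#' @param seed seed for any resampling step (kept in the config hash)
#' @return validated `run_config` list
#' @export
run_config <- function(panel, genotypes, phenotypes, out_dir,
                       outcome = c("pca", "high_grade"),
                       covariates = default_covariates(),
                       missing_policy = c("neutral", "drop_subject"),
                       panel2 = NULL, seed = 1) {
  outcome <- match.arg(outcome)
  missing_policy <- match.arg(missing_policy)
  for (p in c(panel, genotypes, phenotypes, panel2)) {
    if (!file.exists(p)) {
      stop_grsbmi(sprintf("configured path does not exist: %s", p),
                  "grsbmi_config_error")
    }
  }
  structure(list(panel = panel, genotypes = genotypes,
                 phenotypes = phenotypes, out_dir = out_dir,
                 outcome = outcome, covariates = covariates,
                 missing_policy = missing_policy, panel2 = panel2,
                 seed = as.integer(seed)),
            class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

# Hash of the analysis settings plus the *content* of the input files, so a
# re-run from a different directory over identical data hashes identically.
config_hash <- function(config) {
  plain <- list(
    outcome = config$outcome,
    covariates = config$covariates,
    missing_policy = config$missing_policy,
    seed = config$seed,
    inputs = unname(tools::md5sum(c(config$panel, config$genotypes,
                                    config$phenotypes, config$panel2)))
  )
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages: `panel_io` (read and validate inputs), then per panel `grs_engine`
#' (score), `cohort_analysis` (stratify, per-stratum BMI ORs, interaction
#' model, baseline table), then `report`. Any stage error aborts with the
#' stage name in the message. Outputs under `out_dir`: per panel
#' `grs-<name>.csv`, `cohort-<name>.csv`, `baseline_table-<name>.csv`; plus
#' `results.json`, `summary.md` and `run.log`. `results.json` carries no
#' timestamps or absolute paths, so a re-run with the same inputs is
#' byte-identical.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with `results` (the results.json payload) and
#'   `paths` (the files written)
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    stop_grsbmi("config must be built with run_config()", "grsbmi_config_error")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("grsbmi %s on %s", utils::packageVersion("grsbmi"),
            R.version.string),
    sprintf("config hash: %s", config_hash(config)),
    sprintf("outcome: %s; covariates: %s; missing policy: %s",
            config$outcome, paste(config$covariates, collapse = ", "),
            config$missing_policy)
  )
  note <- function(msg) log_lines <<- c(log_lines, msg)

  inputs <- run_stage("panel_io", {
    panels <- list(read_panel(config$panel))
    if (!is.null(config$panel2)) {
      panels <- c(panels, list(read_panel(config$panel2)))
    }
    phenotypes <- read_phenotypes(config$phenotypes)
    list(panels = panels, phenotypes = phenotypes)
  })

  read_geno <- function(panel) {
    if (grepl("\\.vcf(\\.gz)?$", config$genotypes)) {
      read_genotypes_vcf(config$genotypes, panel)
    } else {
      read_genotype_matrix(config$genotypes, panel)
    }
  }

  paths <- character(0)
  panel_results <- list()
  for (panel in inputs$panels) {
    nm <- panel_name(panel)
    genotypes <- run_stage("panel_io", withCallingHandlers(
      read_geno(panel),
      grsbmi_warning = function(w) {
        note(sprintf("[%s] %s", nm, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    ))
    grs <- run_stage("grs_engine", withCallingHandlers(
      compute_grs(genotypes, panel, config$missing_policy),
      grsbmi_warning = function(w) {
        note(sprintf("[%s] %s", nm, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    ))
    res <- run_stage("cohort_analysis", {
      cohort <- build_cohort(grs, inputs$phenotypes)
      strata <- fit_all_strata(cohort, config$outcome, config$covariates)
      interaction <- fit_interaction(cohort, config$outcome, config$covariates)
      btab <- baseline_table(cohort, group_by = "stratum")
      list(cohort = cohort, strata = strata, interaction = interaction,
           baseline = btab)
    })

    grs_path <- file.path(config$out_dir, sprintf("grs-%s.csv", nm))
    utils::write.csv(grs, grs_path, row.names = FALSE, quote = FALSE)
    cohort_path <- file.path(config$out_dir, sprintf("cohort-%s.csv", nm))
    write_cohort_table(res$cohort, cohort_path)
    btab_path <- file.path(config$out_dir,
                           sprintf("baseline_table-%s.csv", nm))
    utils::write.csv(res$baseline, btab_path, row.names = FALSE)
    paths <- c(paths, grs_path, cohort_path, btab_path)

    panel_results[[nm]] <- list(
      panel = nm,
      n_snps = nrow(panel),
      n_subjects = nrow(res$cohort),
      n_cases = sum(res$cohort[[config$outcome]]),
      case_fraction_pct =
        100 * mean(res$cohort[[config$outcome]]),
      mean_grs = mean(res$cohort$grs),
      stratum_fits = strip_fit_attrs(res$strata),
      interaction = strip_fit_attrs(res$interaction)
    )
  }

  results <- list(outcome = config$outcome,
                  covariates = config$covariates,
                  missing_policy = config$missing_policy,
                  config_hash = config_hash(config),
                  panels = panel_results)
  results_path <- file.path(config$out_dir, "results.json")
  run_stage("report", {
    jsonlite::write_json(results, results_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    summary_path <- file.path(config$out_dir, "summary.md")
    writeLines(render_summary(results), summary_path)
    log_path <- file.path(config$out_dir, "run.log")
    writeLines(log_lines, log_path)
    paths <<- c(paths, results_path, summary_path, log_path)
  })
  invisible(list(results = results, paths = paths))
}

strip_fit_attrs <- function(df) {
  attr(df, "model") <- NULL
  attr(df, "coefficients") <- NULL
  df
}

write_cohort_table <- function(cohort, path) {
  out <- cohort
  for (col in intersect(PHENOTYPE_BOOL_COLUMNS, names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Markdown summary shaped like a stratified adjusted-OR table with the
# interaction tests underneath; numbers are taken verbatim from the
# results payload so the rendering cannot drift from results.json.
render_summary <- function(results) {
  fmt <- function(x) sprintf("%.3f", x)
  lines <- c("# Adjusted BMI odds ratios by genetic-risk stratum",
             "",
             sprintf("Outcome: `%s`; adjusted for: %s.", results$outcome,
                     paste(results$covariates, collapse = ", ")))
  for (pr in results$panels) {
    lines <- c(lines, "",
               sprintf("## Panel `%s` (%d SNPs, %d subjects, %d cases, %.2f%% positive)",
                       pr$panel, pr$n_snps, pr$n_subjects, pr$n_cases,
                       pr$case_fraction_pct),
               "",
               "| GRS stratum | n | BMI OR | 95% CI | P |",
               "|---|---|---|---|---|")
    sf <- pr$stratum_fits
    for (i in seq_len(nrow(sf))) {
      lines <- c(lines, sprintf("| %s | %d | %s | %s-%s | %s |",
                                sf$stratum[i], sf$n[i], fmt(sf$bmi_or[i]),
                                fmt(sf$ci_low[i]), fmt(sf$ci_high[i]),
                                fmt(sf$p_value[i])))
    }
    lines <- c(lines, "",
               "| Interaction contrast | OR_interaction | 95% CI | P_interaction |",
               "|---|---|---|---|")
    it <- pr$interaction
    for (i in seq_len(nrow(it))) {
      lines <- c(lines, sprintf("| %s vs %s | %s | %s-%s | %s |",
                                it$contrast[i], it$reference[i],
                                fmt(it$or_interaction[i]), fmt(it$ci_low[i]),
                                fmt(it$ci_high[i]), fmt(it$p_interaction[i])))
    }
  }
  lines
}
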