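#' Stratified BMI odds ratios and BMI-by-genetic-risk interaction
#'
#' Subjects are split into low / intermediate / high genetic-risk strata at
#' the empirical tertiles of the GRS. Within each stratum the per-unit BMI
#' odds ratio on biopsy outcome is estimated by unconditional multiple
#' logistic regression adjusted for conventional risk factors, and a single
#' pooled model with BMI-by-stratum product terms tests whether the BMI
#' effect differs between strata (the gene-environment interaction).
#'
#' @name cohort_analysis
NULL

STRATUM_LEVELS <- c("low", "intermediate", "high")

#' Assign genetic-risk tertile strata
#'
#' Cut points are the empirical 1/3 and 2/3 quantiles (R default quantile
#' type 7). Values strictly below the lower cut are `low`, values in
#' `[q1/3, q2/3)` are `intermediate`, and values at or above the upper cut
#' are `high`; tied values share a stratum. A degenerate distribution whose
#' two cut points coincide is flagged with a warning.
#'
#' @param grs_values numeric vector of GRS values (NA allowed; at least 3
#'   non-missing values required)
#' @return factor with levels `low`, `intermediate`, `high` (NA where the
#'   input is NA)
#' @export
assign_tertiles <- function(grs_values) {
  x <- as.numeric(grs_values)
  if (sum(!is.na(x)) < 3) {
    stop_grsbmi("at least 3 non-missing GRS values are required to form tertiles",
                "grsbmi_insufficient_data")
  }
  q <- stats::quantile(x, probs = c(1 / 3, 2 / 3), na.rm = TRUE,
                       names = FALSE, type = 7)
  if (q[1] == q[2]) {
    warn_grsbmi("degenerate GRS distribution: tertile cut points coincide",
                "grsbmi_degenerate_distribution")
  }
  out <- rep(NA_character_, length(x))
  out[!is.na(x) & x < q[1]] <- "low"
  out[!is.na(x) & x >= q[1] & x < q[2]] <- "intermediate"
  out[!is.na(x) & x >= q[2]] <- "high"
  factor(out, levels = STRATUM_LEVELS)
}

#' Default adjustment covariates
#'
#' The conventional risk factors used for adjustment: age, log-transformed
#' PSA, prostate volume, abnormal DRE finding, and family history of
#' prostate cancer.
#'
#' @return character vector of covariate column names
#' @export
default_covariates <- function() {
  c("age", "log_psa", "prostate_volume", "dre_abnormal", "family_history")
}

#' Merge scores and phenotypes into an analysis cohort
#'
#' Joins the GRS results onto the phenotype table by subject, adds
#' `log_psa = log(psa)`, and assigns GRS tertile strata.
#'
#' @param grs a [compute_grs()] result
#' @param phenotypes a validated phenotype table ([read_phenotypes()])
#' @return data.frame with phenotype columns plus `grs`, `log_grs`,
#'   `log_psa` and `stratum`
#' @export
build_cohort <- function(grs, phenotypes) {
  unmatched <- setdiff(grs$subject_id, phenotypes$subject_id)
  if (length(unmatched) > 0) {
    stop_grsbmi(sprintf("scored subject(s) absent from phenotype table: %s",
                        paste(utils::head(unmatched, 10), collapse = ", ")),
                "grsbmi_validation_error")
  }
  cohort <- merge(phenotypes,
                  grs[, c("subject_id", "grs", "log_grs")],
                  by = "subject_id", all.x = FALSE, all.y = TRUE, sort = TRUE)
  cohort$log_psa <- log(cohort$psa)
  cohort$stratum <- assign_tertiles(cohort$grs)
  cohort
}

# Fit a logistic model, converting separation / non-convergence symptoms into
# a classed fit error.
fit_logistic_guarded <- function(formula, data, context) {
  notes <- character(0)
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  separated <- any(grepl("fitted probabilities numerically 0 or 1", notes))
  if (!fit$converged || separated) {
    stop_grsbmi(sprintf("logistic fit failed in %s: %s", context,
                        if (separated) "quasi-separation detected"
                        else "algorithm did not converge"),
                "grsbmi_fit_error")
  }
  fit
}

check_outcome <- function(y, context) {
  y <- y[!is.na(y)]
  if (length(unique(y)) < 2) {
    stop_grsbmi(sprintf("outcome has a single class in %s", context),
                "grsbmi_degenerate_outcome")
  }
}

wald_row <- function(fit, term) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) {
    stop_grsbmi(sprintf("term '%s' absent from fitted model", term),
                "grsbmi_fit_error")
  }
  b <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  z <- stats::qnorm(0.975)
  list(or = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se),
       p_value = sm[term, "Pr(>|z|)"])
}

#' Adjusted per-stratum BMI odds ratio
#'
#' Maximum-likelihood logistic fit of the outcome on BMI plus adjustment
#' covariates within one genetic-risk stratum. The reported OR is per unit
#' of BMI (kg/m^2) with a Wald 95% CI and p-value.
#'
#' @param cohort a [build_cohort()] table
#' @param stratum one of `"low"`, `"intermediate"`, `"high"`
#' @param outcome `"pca"` (biopsy positive) or `"high_grade"` (aggressive
#'   disease; non-high-grade subjects, including negative biopsies, are the
#'   controls)
#' @param covariates adjustment terms (column names); default
#'   [default_covariates()]
#' @return one-row data.frame `stratum, n, bmi_or, ci_low, ci_high, p_value`
#'   with the fitted model in `attr(, "model")`
#' @export
fit_stratum_bmi_or <- function(cohort, stratum, outcome = c("pca", "high_grade"),
                               covariates = default_covariates()) {
  outcome <- match.arg(outcome)
  stratum <- match.arg(stratum, STRATUM_LEVELS)
  sub <- cohort[!is.na(cohort$stratum) & cohort$stratum == stratum, ,
                drop = FALSE]
  if (nrow(sub) == 0) {
    stop_grsbmi(sprintf("stratum '%s' is empty", stratum),
                "grsbmi_insufficient_data")
  }
  context <- sprintf("stratum '%s'", stratum)
  check_outcome(sub[[outcome]], context)
  fml <- stats::reformulate(c("bmi", covariates), response = outcome)
  fit <- fit_logistic_guarded(fml, sub, context)
  w <- wald_row(fit, "bmi")
  out <- data.frame(stratum = stratum, n = nrow(sub), bmi_or = w$or,
                    ci_low = w$ci_low, ci_high = w$ci_high,
                    p_value = w$p_value, stringsAsFactors = FALSE)
  attr(out, "model") <- fit
  out
}

#' BMI odds ratios for all three strata
#'
#' @inheritParams fit_stratum_bmi_or
#' @return three-row data.frame, one [fit_stratum_bmi_or()] row per stratum
#' @export
fit_all_strata <- function(cohort, outcome = c("pca", "high_grade"),
                           covariates = default_covariates()) {
  outcome <- match.arg(outcome)
  do.call(rbind, lapply(STRATUM_LEVELS, function(s) {
    fit_stratum_bmi_or(cohort, s, outcome, covariates)
  }))
}

#' Test BMI-by-stratum interaction on biopsy outcome
#'
#' Fits a single logistic model with BMI, genetic-risk stratum dummies (low
#' as reference), BMI-by-stratum product terms, and the adjustment
#' covariates. The interaction OR for a contrast stratum is the exponentiated
#' product-term coefficient: the ratio of that stratum's per-unit BMI odds
#' ratio to the low-stratum one. Wald p-values; no multiplicity correction.
#'
#' @inheritParams fit_stratum_bmi_or
#' @return data.frame with one row per non-reference stratum
#'   (`reference, contrast, or_interaction, ci_low, ci_high, p_interaction`),
#'   the fitted model in `attr(, "model")` and the full coefficient vector in
#'   `attr(, "coefficients")`
#' @export
fit_interaction <- function(cohort, outcome = c("pca", "high_grade"),
                            covariates = default_covariates()) {
  outcome <- match.arg(outcome)
  cohort <- cohort[!is.na(cohort$stratum), , drop = FALSE]
  for (s in STRATUM_LEVELS) {
    sub <- cohort[cohort$stratum == s, , drop = FALSE]
    if (nrow(sub) == 0) {
      stop_grsbmi(sprintf("stratum '%s' is empty", s),
                  "grsbmi_insufficient_data")
    }
    check_outcome(sub[[outcome]], sprintf("stratum '%s'", s))
  }
  fml <- stats::reformulate(c("bmi * stratum", covariates), response = outcome)
  fit <- fit_logistic_guarded(fml, cohort, "interaction model")
  contrasts <- STRATUM_LEVELS[-1]
  rows <- lapply(contrasts, function(s) {
    w <- wald_row(fit, paste0("bmi:stratum", s))
    data.frame(reference = "low", contrast = s, or_interaction = w$or,
               ci_low = w$ci_low, ci_high = w$ci_high,
               p_interaction = w$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "model") <- fit
  attr(out, "coefficients") <- stats::coef(fit)
  out
}

#' Baseline characteristics table
#'
#' Continuous variables are summarized as median (IQR) and compared with the
#' Kruskal-Wallis rank test; categorical variables as count (%) of positives
#' compared with the chi-squared test (no continuity correction). A constant
#' variable is reported with p = NA and a warning.
#'
#' @param cohort a [build_cohort()] table
#' @param group_by `"stratum"` (genetic-risk tertiles) or `"outcome"`
#'   (biopsy result)
#' @param continuous,categorical variable names to summarize; defaults cover
#'   the standard biopsy-cohort characteristics present in `cohort`
#' @return data.frame: `variable`, `type`, one summary column per group,
#'   `p_value`, `test`
#' @export
baseline_table <- function(cohort, group_by = c("stratum", "outcome"),
                           continuous = NULL, categorical = NULL) {
  group_by <- match.arg(group_by)
  g <- if (group_by == "stratum") {
    droplevels(cohort$stratum)
  } else {
    factor(ifelse(cohort$pca, "pca", "negative"),
           levels = c("negative", "pca"))
  }
  if (nlevels(g) < 2) {
    stop_grsbmi("baseline table requires at least 2 groups",
                "grsbmi_insufficient_data")
  }
  continuous <- continuous %||%
    intersect(c("age", "bmi", "psa", "prostate_volume", "grs"), names(cohort))
  default_cat <- c("dre_abnormal", "family_history", "smoking", "drinking",
                   "hypertension", "diabetes",
                   if (group_by == "stratum") c("pca", "high_grade"))
  categorical <- categorical %||% intersect(default_cat, names(cohort))

  summarize_one <- function(var, type) {
    x <- cohort[[var]]
    ok <- !is.na(x) & !is.na(g)
    x <- x[ok]; gg <- droplevels(g[ok])
    if (length(unique(x)) < 2) {
      warn_grsbmi(sprintf("variable '%s' is constant; p-value set to NA", var),
                  "grsbmi_constant_variable")
      p <- NA_real_
    } else if (type == "continuous") {
      p <- stats::kruskal.test(x, gg)$p.value
    } else {
      p <- suppressWarnings(
        stats::chisq.test(table(gg, x), correct = FALSE)$p.value
      )
    }
    cells <- vapply(levels(g), function(lev) {
      xi <- x[gg == lev]
      if (type == "continuous") {
        q <- stats::quantile(xi, c(0.5, 0.25, 0.75), names = FALSE)
        sprintf("%.2f (%.2f-%.2f)", q[1], q[2], q[3])
      } else {
        sprintf("%d (%.1f%%)", sum(xi), 100 * mean(xi))
      }
    }, character(1))
    c(variable = var, type = type, cells,
      p_value = if (is.na(p)) NA_character_ else sprintf("%.4g", p),
      test = if (type == "continuous") "kruskal-wallis" else "chi-squared")
  }

  rows <- c(lapply(continuous, summarize_one, type = "continuous"),
            lapply(categorical, summarize_one, type = "categorical"))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  out$p_value <- as.numeric(out$p_value)
  rownames(out) <- NULL
  out
}
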