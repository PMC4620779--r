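test_that("tertile assignment splits at the empirical 1/3 and 2/3 quantiles", {
  s <- assign_tertiles(1:9)
  expect_equal(as.character(s),
               rep(c("low", "intermediate", "high"), each = 3))

  # degenerate distribution: everything ties into the top stratum
  expect_warning(deg <- assign_tertiles(rep(1, 6)),
                 class = "grsbmi_degenerate_distribution")
  expect_true(all(deg == "high"))

  expect_error(assign_tertiles(c(1, 2)), class = "grsbmi_insufficient_data")

  # a large continuous sample splits 333 / 333 / 334
  set.seed(99)
  x <- exp(rnorm(1000, 0, 0.3))
  sizes <- table(assign_tertiles(x))
  expect_true(all(abs(sizes - c(333, 333, 334)) <= 1))

  # idempotent and order-independent
  perm <- sample(length(x))
  expect_equal(assign_tertiles(x)[perm], assign_tertiles(x[perm]))
})

test_that("stratum BMI fit recovers null and non-null simulated slopes", {
  make_stratum <- function(n, beta, seed) {
    set.seed(seed)
    bmi <- rnorm(n, 24, 3)
    data.frame(bmi = bmi,
               pca = runif(n) < plogis(-0.3 + beta * (bmi - 24)),
               stratum = factor("high", levels = c("low", "intermediate",
                                                   "high")))
  }

  null_fit <- fit_stratum_bmi_or(make_stratum(2000, 0, 1), "high",
                                 covariates = character(0))
  expect_true(null_fit$ci_low < 1 && 1 < null_fit$ci_high)
  expect_equal(null_fit$bmi_or, 1, tolerance = 0.05)
  expect_equal(null_fit$n, 2000)

  truth <- log(1.2)
  alt_fit <- fit_stratum_bmi_or(make_stratum(2000, truth, 2), "high",
                                covariates = character(0))
  expect_true(alt_fit$ci_low < 1.2 && 1.2 < alt_fit$ci_high)

  # degenerate outcome: a stratum with only cases cannot be fit
  allcase <- make_stratum(100, 0, 3)
  allcase$pca <- TRUE
  expect_error(fit_stratum_bmi_or(allcase, "high", covariates = character(0)),
               class = "grsbmi_degenerate_outcome")
})

test_that("interaction model agrees with stratum fits in the saturated case", {
  cfg <- sim_config(n_subjects = 3000, seed = 21)
  sim <- simulate_cohort(cfg)
  cohort <- build_cohort(sim$grs, sim$phenotypes)

  it <- fit_interaction(cohort, covariates = character(0))
  fit <- attr(it, "model")
  cf <- coef(fit)

  # exponentiated product term IS the reported interaction OR
  expect_equal(it$or_interaction[it$contrast == "high"],
               unname(exp(cf["bmi:stratumhigh"])), tolerance = 1e-9)

  # with stratum-specific intercepts and slopes and no covariates, the
  # pooled model's per-stratum slope equals the stratum-only fit
  for (s in c("intermediate", "high")) {
    pooled_or <- exp(cf["bmi"] + cf[paste0("bmi:stratum", s)])
    alone <- fit_stratum_bmi_or(cohort, s, covariates = character(0))
    expect_equal(unname(pooled_or), alone$bmi_or, tolerance = 1e-8)
  }
  low_alone <- fit_stratum_bmi_or(cohort, "low", covariates = character(0))
  expect_equal(unname(exp(cf["bmi"])), low_alone$bmi_or, tolerance = 1e-8)
})

test_that("a null interaction yields interaction ORs near 1", {
  cfg <- sim_config(n_subjects = 5000, seed = 33,
                    beta_bmi_by_stratum = c(0.08, 0.08, 0.08))
  sim <- simulate_cohort(cfg)
  cohort <- build_cohort(sim$grs, sim$phenotypes)
  it <- fit_interaction(cohort)
  expect_true(all(it$ci_low < 1 & 1 < it$ci_high))
  expect_equal(it$or_interaction, c(1, 1), tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("shifting BMI by a constant changes no odds ratio", {
  cfg <- sim_config(n_subjects = 2000, seed = 12)
  sim <- simulate_cohort(cfg)
  cohort <- build_cohort(sim$grs, sim$phenotypes)
  shifted <- cohort
  shifted$bmi <- shifted$bmi + 5

  a <- fit_all_strata(cohort)
  b <- fit_all_strata(shifted)
  expect_equal(a$bmi_or, b$bmi_or, tolerance = 1e-8)

  ia <- fit_interaction(cohort)
  ib <- fit_interaction(shifted)
  expect_equal(ia$or_interaction, ib$or_interaction, tolerance = 1e-8)
  expect_equal(ia$p_interaction, ib$p_interaction, tolerance = 1e-6)
})

test_that("baseline table computes rank and chi-squared comparisons", {
  # two groups with identical data: statistics 0, p-values 1
  block <- make_phenotypes(80)
  twin <- rbind(transform(block, pca = FALSE),
                transform(block, pca = TRUE))
  twin$subject_id <- sprintf("S%04d", seq_len(nrow(twin)))
  twin$high_grade <- twin$high_grade & twin$pca
  twin$grs <- rep(block$bmi, 2)  # any identical continuous column
  twin$stratum <- assign_tertiles(twin$grs)
  tab <- baseline_table(twin, group_by = "outcome",
                        continuous = c("age", "bmi", "psa"),
                        categorical = c("smoking", "hypertension"))
  expect_true(all(abs(tab$p_value - 1) < 1e-9))

  # a 5-SD location shift is overwhelmingly detected
  shift <- twin
  shift$age[shift$pca] <- shift$age[shift$pca] + 5 * sd(shift$age)
  tab2 <- baseline_table(shift, group_by = "outcome", continuous = "age",
                         categorical = character(0))
  expect_lt(tab2$p_value, 0.001)

  # balanced 2x2 table: chi-squared statistic 0, p = 1
  bal <- twin[1:100, ]
  bal$pca <- rep(c(TRUE, FALSE), 50)
  bal$smoking <- rep(c(TRUE, TRUE, FALSE, FALSE), 25)
  bal$high_grade <- bal$high_grade & bal$pca
  tab3 <- baseline_table(bal, group_by = "outcome",
                         continuous = character(0), categorical = "smoking")
  expect_equal(tab3$p_value, 1)

  # constant variable: NA p-value plus a warning
  const <- twin
  const$diabetes <- FALSE
  expect_warning(
    tab4 <- baseline_table(const, group_by = "outcome",
                           continuous = character(0),
                           categorical = "diabetes"),
    class = "grsbmi_constant_variable"
  )
  expect_true(is.na(tab4$p_value))
})

test_that("high-grade outcome contrasts aggressive disease against the rest", {
  cfg <- sim_config(n_subjects = 3000, seed = 44, p_high_grade = 0.5)
  sim <- simulate_cohort(cfg)
  cohort <- build_cohort(sim$grs, sim$phenotypes)
  fit <- fit_stratum_bmi_or(cohort, "high", outcome = "high_grade")
  expect_equal(fit$n, sum(cohort$stratum == "high"))
  it <- fit_interaction(cohort, outcome = "high_grade")
  expect_equal(nrow(it), 2)
  expect_true(all(it$or_interaction > 0))
})
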