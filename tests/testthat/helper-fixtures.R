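# Small in-code fixtures shared across the suite.

# Panel with non-palindromic alleles so VCF round-trips are unambiguous.
tiny_panel <- function(ors = c(1.5, 1.2), freqs = c(0.3, 0.5), name = "tiny") {
  k <- length(ors)
  snp_panel(data.frame(
    rsid = sprintf("rs%03d", seq_len(k)),
    chrom = as.character(seq_len(k)),
    pos = seq_len(k) * 100L,
    risk_allele = rep(c("A", "T"), length.out = k),
    other_allele = rep(c("G", "C"), length.out = k),
    allelic_or = ors,
    risk_allele_freq = freqs,
    stringsAsFactors = FALSE
  ), name = name)
}

# Independent brute-force GRS for one subject: plain arithmetic, no log
# space, no shared code with compute_grs.
oracle_grs <- function(counts, ors, freqs) {
  prod(mapply(function(cnt, or, p) {
    g_or <- or^(0:2)
    f <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    rel <- g_or / sum(g_or * f)
    rel[cnt + 1]
  }, counts, ors, freqs))
}

# Genotype matrix with explicit counts; rows subjects, cols panel rsids.
counts_matrix <- function(counts, panel, subjects = NULL) {
  m <- matrix(as.integer(counts), ncol = nrow(panel), byrow = TRUE)
  rownames(m) <- subjects %||% sprintf("S%03d", seq_len(nrow(m)))
  colnames(m) <- panel$rsid
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal well-formed phenotype data.frame.
make_phenotypes <- function(n, subjects = sprintf("S%03d", seq_len(n)),
                            seed = 11) {
  set.seed(seed)
  data.frame(
    subject_id = subjects,
    age = round(rnorm(n, 66, 7), 1),
    bmi = round(rnorm(n, 24, 3), 1),
    psa = round(exp(rnorm(n, log(10), 0.8)), 2),
    prostate_volume = round(pmax(rnorm(n, 42, 15), 12), 1),
    dre_abnormal = runif(n) < 0.25,
    family_history = runif(n) < 0.05,
    smoking = runif(n) < 0.45,
    drinking = runif(n) < 0.3,
    hypertension = runif(n) < 0.3,
    diabetes = runif(n) < 0.12,
    pca = runif(n) < 0.43,
    stringsAsFactors = FALSE
  ) -> df
  df$high_grade <- df$pca & runif(n) < 0.4
  df
}

# Run the simulate -> score -> stratify -> interaction pipeline once and
# return the high-vs-low interaction row; used by the replicate studies.
one_interaction_rep <- function(seed, n, beta_bmi, panel) {
  cfg <- sim_config(n_subjects = n, panel = panel, seed = seed,
                    beta_bmi_by_stratum = beta_bmi)
  sim <- simulate_cohort(cfg)
  cohort <- build_cohort(sim$grs, sim$phenotypes)
  it <- fit_interaction(cohort)
  it[it$contrast == "high", ]
}
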