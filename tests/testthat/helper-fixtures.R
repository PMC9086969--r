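# One moderately large simulation shared across test files (generated
# lazily, once per test run).
.fixture_env <- new.env(parent = emptyenv())

big_sim <- function() {
  if (is.null(.fixture_env$big)) {
    cfg <- sim_config(n = 50000, m_snps = 200, n_causal = 50,
                      h2_snp = 0.3, c2_shared = 0.1, seed = 20260901L)
    .fixture_env$big <- generate_cohort(cfg)
  }
  .fixture_env$big
}

# Cohort with the oracle (true genetic) score attached as the PGS.
big_cohort_with_true_score <- function() {
  sim <- big_sim()
  cohort <- sim$cohort
  g <- sim$truth$liability_genetic
  cohort$pgs_raw <- g
  cohort$pgs_std <- (g - mean(g)) / sd(g)
  cohort
}
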