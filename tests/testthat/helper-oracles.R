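# Independent oracles used across the suite.

# Hudson Fst estimator ("ratio of averages") computed from two genotype
# matrices, one per population. Independent of the simulator's internals.
hudson_fst <- function(g1, g2) {
  n1 <- nrow(g1)
  n2 <- nrow(g2)
  p1 <- colMeans(g1) / 2
  p2 <- colMeans(g2) / 2
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / (2 * n1 - 1) - p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Exact pmf over {0,1,2} of Bern(p1/2) + Bern(p2/2) for one SNP.
trio_twin_pmf <- function(p1, p2) {
  a <- p1 / 2
  b <- p2 / 2
  c((1 - a) * (1 - b), a * (1 - b) + (1 - a) * b, a * b)
}

# Exact joint distribution of the twin genotype configuration for a set of
# trio families at independent SNPs: every configuration (one genotype per
# family x SNP cell) with its probability, by full enumeration.
enumerate_trio_configs <- function(parent1, parent2) {
  cells <- expand.grid(rep(list(0:2), length(parent1)))
  pmfs <- mapply(trio_twin_pmf, as.vector(parent1), as.vector(parent2))
  probs <- apply(cells, 1, function(g)
    prod(pmfs[cbind(g + 1, seq_along(g))]))
  list(configs = as.matrix(cells), probs = probs)
}

# Small confounded-null simulated dataset + summary stats for quick tests.
tiny_dataset <- function(seed = 1, n_external = 2000, n_families = 100,
                         m_snps = 20, m_causal = 10, gamma = 0.8,
                         beta_EO = 0) {
  cfg <- sim_config(n_external = n_external, n_families = n_families,
                    m_snps = m_snps, m_causal = m_causal,
                    gamma_confound = gamma, beta_causal_EO = beta_EO,
                    seed = seed)
  dat <- simulate_mr_data(cfg)
  ss <- suppressWarnings(
    gwas_summary_stats(dat$external$genotypes, dat$external$exposure,
                       dat$external$outcome))
  list(dat = dat, ss = ss)
}

# Hand-built summary-stats table.
stats_table <- function(beta_exposure, beta_outcome,
                        se_exposure = rep(0.05, length(beta_exposure)),
                        se_outcome = rep(0.05, length(beta_exposure)),
                        p_exposure = rep(1e-8, length(beta_exposure))) {
  data.frame(snp_id = paste0("snp", seq_along(beta_exposure)),
             beta_exposure = beta_exposure, se_exposure = se_exposure,
             p_exposure = p_exposure, beta_outcome = beta_outcome,
             se_outcome = se_outcome, stringsAsFactors = FALSE)
}
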