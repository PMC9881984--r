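test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(fst = -0.1), "fst")
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(m_snps = 10, m_causal = 20), "m_causal")
  expect_error(sim_config(ancestral_freq_range = c(0, 0.9)), "ancestral")
  expect_error(sim_config(ancestral_freq_range = c(0.9, 0.1)), "ancestral")
  expect_error(sim_config(beta_causal_EO = 1.5), "negative")
})

test_that("Fst = 0 collapses both populations onto the ancestral frequencies", {
  set.seed(1)
  cfg <- sim_config(n_external = 50, n_families = 10, m_snps = 30,
                    m_causal = 10, fst = 0)
  gen <- simulate_genotypes(cfg)
  expect_identical(gen$freqs[1, ], gen$freqs[2, ])
  expect_identical(gen$freqs[1, ], gen$p_anc)
})

test_that("genotype matrices have the configured shape and 0/1/2 entries", {
  set.seed(2)
  cfg <- sim_config(n_external = 500, n_families = 40, m_snps = 25,
                    m_causal = 10)
  gen <- simulate_genotypes(cfg)
  expect_equal(dim(gen$external), c(500, 25))
  expect_equal(dim(gen$parent1), c(40, 25))
  expect_equal(dim(gen$parent2), c(40, 25))
  expect_true(all(gen$external %in% 0:2))
  expect_true(all(gen$parent1 %in% 0:2))
  expect_equal(sum(gen$pop_external == 0), 250)
  expect_equal(sum(gen$pop_families == 1), 20)
})

test_that("simulated divergence matches the Hudson Fst oracle", {
  set.seed(3)
  cfg <- sim_config(n_external = 20000, n_families = 1, m_snps = 200,
                    m_causal = 1, fst = 0.01, pop_split = 0.5)
  gen <- simulate_genotypes(cfg)
  fhat <- hudson_fst(gen$external[gen$pop_external == 0, ],
                     gen$external[gen$pop_external == 1, ])
  expect_lt(abs(fhat - 0.01), 0.005)
})

test_that("between-population divergence grows with Fst", {
  set.seed(4)
  div <- vapply(c(0, 0.01, 0.05, 0.1), function(f) {
    cfg <- sim_config(n_external = 2, n_families = 1, m_snps = 500,
                      m_causal = 1, fst = f)
    gen <- simulate_genotypes(cfg)
    mean(abs(gen$freqs[1, ] - gen$freqs[2, ]))
  }, 0)
  expect_true(all(diff(div) > 0))
})

test_that("offspring sampling follows the Mendelian transmission law", {
  expect_equal(sample_offspring(c(2, 2, 2), c(2, 2, 2)), c(2, 2, 2))
  expect_equal(sample_offspring(rep(0, 5), rep(2, 5)), rep(1, 5))
  expect_equal(sample_offspring(rep(0, 5), rep(0, 5)), rep(0, 5))
  set.seed(5)
  draws <- sample_offspring(rep(1, 1e5), rep(1, 1e5))
  freq <- tabulate(draws + 1, 3) / 1e5
  # Bern(1/2) + Bern(1/2) enumerates to {0: 1/4, 1: 1/2, 2: 1/4}
  expect_lt(max(abs(freq - c(0.25, 0.5, 0.25))), 0.01)
  expect_error(sample_offspring(c(0, 3), c(0, 0)), "invalid genotype")
})

test_that("simulated offspring are always Mendelian-consistent", {
  set.seed(6)
  cfg <- sim_config(n_external = 10, n_families = 300, m_snps = 40,
                    m_causal = 10)
  gen <- simulate_genotypes(cfg)
  off <- sample_offspring(gen$parent1, gen$parent2)
  lo <- (gen$parent1 == 2) + (gen$parent2 == 2)
  hi <- (gen$parent1 > 0) + (gen$parent2 > 0)
  expect_true(all(off >= lo & off <= hi))
  # family_set performs the same check on construction
  expect_s3_class(family_set("trio", offspring = off, parent1 = gen$parent1,
                             parent2 = gen$parent2, outcome = rnorm(300)),
                  "family_set")
})

test_that("genetic component of the exposure explains h2 of its variance", {
  set.seed(7)
  cfg <- sim_config(n_external = 50000, n_families = 1, m_snps = 50,
                    m_causal = 25, h2 = 0.2, gamma_confound = 0)
  gen <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gen$external, gen$pop_external, cfg)
  # OLS of the exposure on the causal SNPs as the oracle for explained variance
  fit <- lm(ph$exposure ~ gen$external[, 1:25])
  expect_lt(abs(summary(fit)$r.squared - 0.2), 0.02)
  expect_lt(abs(var(ph$exposure) - 1), 0.05)
})

test_that("phenotype confounding behaves as configured", {
  set.seed(8)
  cfg0 <- sim_config(n_external = 50000, n_families = 1, m_snps = 10,
                     m_causal = 0, h2 = 0, gamma_confound = 0,
                     beta_causal_EO = 0)
  gen <- simulate_genotypes(cfg0)
  ph0 <- simulate_phenotypes(gen$external, gen$pop_external, cfg0)
  expect_lt(abs(cor(ph0$exposure, ph0$outcome)), 0.02)
  expect_lt(abs(cor(ph0$exposure, gen$pop_external)), 0.02)

  cfg8 <- sim_config(n_external = 50000, n_families = 1, m_snps = 10,
                     m_causal = 0, h2 = 0, gamma_confound = 0.8,
                     beta_causal_EO = 0)
  ph8 <- simulate_phenotypes(gen$external, gen$pop_external, cfg8)
  # population label drives both traits: a confounded null
  expect_gt(cor(ph8$exposure, ph8$outcome), 0.05)
})

test_that("h2 = 0 with causal SNPs yields an all-zero genetic architecture", {
  set.seed(9)
  cfg <- sim_config(n_external = 100, n_families = 1, m_snps = 10,
                    m_causal = 5, h2 = 0)
  gen <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gen$external, gen$pop_external, cfg)
  expect_equal(ph$beta_XE, rep(0, 10))
})

test_that("a fixed seed reproduces the dataset bit for bit", {
  cfg <- sim_config(n_external = 200, n_families = 30, m_snps = 15,
                    m_causal = 5, gamma_confound = 0.4, seed = 77)
  d1 <- simulate_mr_data(cfg)
  d2 <- simulate_mr_data(cfg)
  expect_identical(d1$external$genotypes, d2$external$genotypes)
  expect_identical(d1$families$offspring, d2$families$offspring)
  expect_identical(d1$external$exposure, d2$external$exposure)
  expect_identical(d1$true_beta_XE, d2$true_beta_XE)
})
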