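test_that("ratio estimator arithmetic and errors", {
  st <- stats_table(beta_exposure = 0.2, beta_outcome = 0.4,
                    se_outcome = 0.1)
  est <- mr_ratio(st)
  expect_equal(est$beta_EO, 2)
  expect_equal(est$se, 0.1 / 0.2)
  st0 <- stats_table(beta_exposure = 0.2, beta_outcome = 0)
  expect_equal(mr_ratio(st0)$beta_EO, 0)
  expect_error(mr_ratio(stats_table(beta_exposure = 0, beta_outcome = 1)),
               "zero")
  expect_error(mr_ratio(stats_table(beta_exposure = c(1, 1),
                                    beta_outcome = c(1, 1))), "single")
})

test_that("IVW with one instrument reduces exactly to the ratio estimator", {
  st <- stats_table(beta_exposure = 0.13, beta_outcome = -0.07,
                    se_outcome = 0.021)
  ivw <- mr_ivw(st)
  ratio <- mr_ratio(st)
  expect_equal(ivw$beta_EO, ratio$beta_EO, tolerance = 1e-15)
  expect_equal(ivw$se, ratio$se, tolerance = 1e-15)
})

test_that("IVW returns the common ratio whenever all ratios agree", {
  set.seed(1)
  bxe <- runif(8, 0.05, 0.3)
  st <- stats_table(beta_exposure = bxe, beta_outcome = 0.37 * bxe,
                    se_outcome = runif(8, 0.01, 0.1))
  expect_equal(mr_ivw(st)$beta_EO, 0.37, tolerance = 1e-12)
})

test_that("IVW is invariant to joint sign flips and rejects null instruments", {
  set.seed(2)
  bxe <- rnorm(10, 0, 0.2)
  bxo <- 0.1 * bxe + rnorm(10, 0, 0.02)
  st <- stats_table(beta_exposure = bxe, beta_outcome = bxo)
  flip <- rep(c(1, -1), 5)
  st_f <- stats_table(beta_exposure = bxe * flip, beta_outcome = bxo * flip)
  expect_equal(mr_ivw(st)$beta_EO, mr_ivw(st_f)$beta_EO, tolerance = 1e-12)

  st_bad <- stats_table(beta_exposure = c(0.2, 0), beta_outcome = c(0.1, 5))
  expect_warning(est <- mr_ivw(st_bad), "rejected")
  expect_equal(est$n_instruments, 1)
})

test_that("Egger recovers slope and intercept exactly on noise-free data", {
  set.seed(3)
  bxe <- runif(6, 0.1, 0.5)
  st <- stats_table(beta_exposure = bxe, beta_outcome = 0.2 * bxe,
                    se_outcome = runif(6, 0.02, 0.08))
  est <- mr_egger(st)
  expect_equal(est$beta_EO, 0.2, tolerance = 1e-10)
  expect_equal(est$intercept, 0, tolerance = 1e-10)

  # a constant directional shift is absorbed by the intercept
  st_shift <- st
  st_shift$beta_outcome <- st$beta_outcome + 0.05
  est_s <- mr_egger(st_shift)
  expect_equal(est_s$beta_EO, 0.2, tolerance = 1e-10)
  expect_equal(est_s$intercept, 0.05, tolerance = 1e-10)

  expect_error(mr_egger(stats_table(beta_exposure = c(1, 1),
                                    beta_outcome = c(1, 1))), ">= 3")
})

test_that("Egger equals IVW when the fitted intercept is exactly zero", {
  bxe <- c(0.1, 0.2, 0.4, 0.25)
  st <- stats_table(beta_exposure = bxe, beta_outcome = 0.15 * bxe,
                    se_outcome = c(0.03, 0.05, 0.02, 0.04))
  eg <- mr_egger(st)
  expect_equal(eg$intercept, 0, tolerance = 1e-12)
  expect_equal(eg$beta_EO, mr_ivw(st)$beta_EO, tolerance = 1e-10)
})

test_that("single strong instrument matches the 2SLS oracle and the truth", {
  set.seed(4)
  cfg <- sim_config(n_external = 50000, n_families = 1, m_snps = 1,
                    m_causal = 1, h2 = 0.2, beta_causal_EO = 0.3,
                    gamma_confound = 0)
  gen <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gen$external, gen$pop_external, cfg)
  ss <- gwas_summary_stats(gen$external, ph$exposure, ph$outcome)
  est <- mr_ratio(ss)
  # two-stage least squares on the individual-level data as the oracle
  e_hat <- fitted(lm(ph$exposure ~ gen$external[, 1]))
  tsls <- coef(lm(ph$outcome ~ e_hat))[2]
  expect_lt(abs(est$beta_EO - 0.3), 0.05)
  expect_equal(est$beta_EO, unname(tsls), tolerance = 1e-6)
})
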