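test_that("the prediction statistic matches hand arithmetic", {
  # one individual, one SNP: E_hat = 0.5 * 2 = 1, O_hat = 2 * 1 = 2, O = 2
  expect_equal(mrtwin_statistic(matrix(2, 1, 1), 2, 0.5, 2), 0)
  # three individuals on one SNP, beta_XE = beta_EO = 1
  x <- matrix(c(0, 1, 2), 3, 1)
  expect_equal(mrtwin_statistic(x, c(0, 1, 2), 1, 1), 0)
  expect_equal(mrtwin_statistic(x, c(1, 1, 1), 1, 1), -2)
})

test_that("statistic validates alignment and finiteness", {
  x <- matrix(0:2, 3, 1, dimnames = list(NULL, "snpA"))
  expect_error(mrtwin_statistic(x, c(0, 1, 2), c(1, 1), 1), "aligned")
  expect_error(mrtwin_statistic(x, c(0, 1, 2),
                                c(snpB = 1), 1), "names")
  expect_error(mrtwin_statistic(x, c(0, NA, 2), 1, 1), "non-finite")
  expect_error(mrtwin_statistic(x, c(0, 1), 1, 1), "length")
})

test_that("statistic is invariant to family order", {
  set.seed(1)
  g <- matrix(rbinom(60, 2, 0.5), 20, 3)
  o <- rnorm(20)
  bxe <- runif(3)
  perm <- sample(20)
  expect_equal(mrtwin_statistic(g, o, bxe, 0.4),
               mrtwin_statistic(g[perm, ], o[perm], bxe, 0.4))
})

test_that("beta_EO = 0 makes the statistic constant and p exactly 1", {
  tiny <- tiny_dataset(seed = 2, n_families = 30, m_snps = 10, m_causal = 5)
  st <- tiny$ss
  st$beta_outcome <- 0  # forces IVW estimate (and thus every O_hat) to zero
  fit <- mrtwin(tiny$dat$families, st, instruments = st$snp_id, B = 50,
                seed = 3)
  expect_equal(fit$estimate$beta_EO, 0)
  expect_equal(fit$p_value, 1)
  expect_true(all(fit$t_null == fit$t_star))
})

test_that("p-values live on the grid k/(B+1) and respect the floor", {
  tiny <- tiny_dataset(seed = 4, n_families = 40, m_snps = 12, m_causal = 6,
                       gamma = 0.4)
  for (B in c(19, 99)) {
    fit <- mrtwin(tiny$dat$families, tiny$ss, B = B, seed = 5,
                  bonferroni_alpha = Inf)
    expect_true(fit$p_value %in% (seq_len(B + 1) / (B + 1)))
    expect_gte(fit$p_value, 1 / (B + 1))
  }
})

test_that("a strong causal effect drives p to the attainable floor", {
  strong <- tiny_dataset(seed = 6, n_external = 10000, n_families = 200,
                         m_snps = 50, m_causal = 25, gamma = 0,
                         beta_EO = 0.5)
  fit <- mrtwin(strong$dat$families, strong$ss, B = 99, seed = 7)
  expect_equal(fit$p_value, 1 / 100)
})

test_that("the twin randomization is reproducible from the seed", {
  tiny <- tiny_dataset(seed = 8, n_families = 25, m_snps = 10, m_causal = 5)
  f1 <- mrtwin(tiny$dat$families, tiny$ss, B = 40, seed = 11,
               bonferroni_alpha = Inf, chunk_size = 4)
  f2 <- mrtwin(tiny$dat$families, tiny$ss, B = 40, seed = 11,
               bonferroni_alpha = Inf, chunk_size = 40)
  expect_identical(f1$t_null, f2$t_null)
  expect_identical(f1$p_value, f2$p_value)
})

test_that("two-sided option stays on the grid and is never smaller than 2/(B+1)", {
  tiny <- tiny_dataset(seed = 9, n_families = 30, m_snps = 10, m_causal = 5)
  fit <- mrtwin(tiny$dat$families, tiny$ss, B = 49, seed = 10,
                bonferroni_alpha = Inf, two_sided = TRUE)
  expect_gte(fit$p_value, 2 / 50)
  expect_lte(fit$p_value, 1)
})

test_that("instruments missing from the family genotypes are an error", {
  tiny <- tiny_dataset(seed = 12, n_families = 20, m_snps = 8, m_causal = 4)
  st <- tiny$ss
  st$snp_id[1] <- "rs_not_in_families"
  expect_error(mrtwin(tiny$dat$families, st, instruments = st$snp_id[1:3],
                      B = 10),
               "absent from the family genotypes")
})

test_that("duo and sibling designs run end to end under the null", {
  tiny <- tiny_dataset(seed = 13, n_families = 60, m_snps = 15, m_causal = 8,
                       gamma = 0.4)
  fam <- tiny$dat$families
  duo <- family_set("duo", offspring = fam$offspring, parent1 = fam$parent1,
                    outcome = fam$outcome, snp_ids = fam$snp_ids)
  sib2 <- sample_offspring(fam$parent1, fam$parent2)
  sibs <- lapply(seq_len(nrow(fam$offspring)), function(n)
    rbind(fam$offspring[n, ], sib2[n, ]))
  sib <- family_set("sibling", siblings = sibs, outcome = fam$outcome,
                    snp_ids = fam$snp_ids)
  for (f in list(duo, sib)) {
    fit <- mrtwin(f, tiny$ss, B = 30, seed = 14, bonferroni_alpha = Inf)
    expect_true(fit$p_value %in% (seq_len(31) / 31))
  }
})

test_that("print, summary, and plot methods run", {
  tiny <- tiny_dataset(seed = 15, n_families = 20, m_snps = 8, m_causal = 4)
  fit <- mrtwin(tiny$dat$families, tiny$ss, B = 20, seed = 16,
                bonferroni_alpha = Inf)
  expect_output(print(fit), "MR-Twin")
  expect_output(print(summary(fit)), "rank")
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})
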