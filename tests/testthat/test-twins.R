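test_that("trio twin law matches hand-enumerated tables", {
  expect_equal(sample_twin_trio(c(0, 0), c(0, 0)), c(0, 0))
  expect_equal(sample_twin_trio(2, 2), 2)
  set.seed(1)
  draws <- replicate(4e4, sample_twin_trio(1, 2))
  freq <- tabulate(draws + 1, 3) / 4e4
  # Bern(1/2) + Bern(1): {1: 1/2, 2: 1/2}
  expect_lt(max(abs(freq - c(0, 0.5, 0.5))), 0.02)
})

test_that("duo twin law fixes the unobserved parent's allele", {
  # homozygous observed parent at every SNP: twin equals the offspring
  p <- c(0, 0, 2, 2)
  x <- c(0, 1, 1, 2)
  for (i in 1:5) expect_equal(sample_twin_duo(p, x), x)

  set.seed(2)
  d_het2 <- replicate(4e4, sample_twin_duo(1, 2))
  freq <- tabulate(d_het2 + 1, 3) / 4e4
  expect_lt(max(abs(freq - c(0, 0.5, 0.5))), 0.02)  # Bern(1/2) + Bern(1)

  d_het0 <- replicate(4e4, sample_twin_duo(1, 0))
  freq0 <- tabulate(d_het0 + 1, 3) / 4e4
  expect_lt(max(abs(freq0 - c(0.5, 0.5, 0))), 0.02) # Bern(1/2) + Bern(0)

  expect_error(sample_twin_duo(1, NULL), "offspring")
  expect_error(sample_twin_duo(2, 0), "inconsistent")
})

test_that("sibling twin law resamples the pooled alleles", {
  sibs22 <- rbind(c(2), c(2))
  for (i in 1:5) expect_equal(sample_twin_sibling(sibs22), 2)

  set.seed(3)
  sibs02 <- rbind(0, 2)  # pooled alleles {0,0,1,1}
  draws <- replicate(4e4, sample_twin_sibling(sibs02))
  freq <- tabulate(draws + 1, 3) / 4e4
  expect_lt(max(abs(freq - c(0.25, 0.5, 0.25))), 0.02)

  draws_p <- replicate(4e4, sample_twin_sibling(sibs02, method = "pairs"))
  # one allele from each distinct sibling: Bern(0) + Bern(1) = 1 always
  expect_true(all(draws_p == 1))

  expect_error(sample_twin_sibling(matrix(1, 1, 3)), ">= 2")
})

test_that("twin batches are deterministic and chunk-invariant", {
  set.seed(4)
  n <- 12
  m <- 6
  p1 <- matrix(rbinom(n * m, 2, 0.5), n, m)
  p2 <- matrix(rbinom(n * m, 2, 0.5), n, m)
  off <- sample_offspring(p1, p2)
  fam <- family_set("trio", offspring = off, parent1 = p1, parent2 = p2,
                    outcome = rnorm(n))
  b1 <- generate_twin_batch(fam, B = 21, seed = 9, chunk_size = 1)
  b2 <- generate_twin_batch(fam, B = 21, seed = 9, chunk_size = 7)
  b3 <- generate_twin_batch(fam, B = 21, seed = 9, chunk_size = 21)
  expect_identical(b1, b2)
  expect_identical(b1, b3)
  expect_equal(dim(b1), c(21, n, m))
  expect_true(all(b1 %in% 0:2))

  dfam <- family_set("duo", offspring = off, parent1 = p1, outcome = rnorm(n))
  expect_identical(generate_twin_batch(dfam, 13, seed = 2, chunk_size = 3),
                   generate_twin_batch(dfam, 13, seed = 2, chunk_size = 13))
})

test_that("trio twin genotype means converge to (P1 + P2) / 2", {
  set.seed(5)
  n <- 5
  m <- 4
  p1 <- matrix(rbinom(n * m, 2, 0.5), n, m)
  p2 <- matrix(rbinom(n * m, 2, 0.5), n, m)
  fam <- family_set("trio", offspring = sample_offspring(p1, p2),
                    parent1 = p1, parent2 = p2, outcome = rnorm(n))
  b <- generate_twin_batch(fam, B = 4000, seed = 6)
  emp_mean <- apply(b, c(2, 3), mean)
  expect_lt(max(abs(emp_mean - (p1 + p2) / 2)), 0.05)
})

test_that("Monte-Carlo twin configurations match the enumeration oracle", {
  p1 <- rbind(c(1, 2), c(0, 1))  # 2 trios x 2 SNPs
  p2 <- rbind(c(1, 1), c(2, 1))
  fam <- family_set("trio",
                    offspring = sample_offspring(p1, p2),
                    parent1 = p1, parent2 = p2, outcome = c(0, 0))
  oracle <- enumerate_trio_configs(p1, p2)
  set.seed(7)
  b <- generate_twin_batch(fam, B = 1e5)
  flat <- cbind(b[, 1, 1], b[, 2, 1], b[, 1, 2], b[, 2, 2])
  code <- flat %*% c(1, 3, 9, 27)
  oracle_code <- oracle$configs %*% c(1, 3, 9, 27)
  counts <- tabulate(code + 1, 81)
  keep <- oracle$probs > 0
  # every observed configuration must be possible under the oracle
  expect_true(all(counts[setdiff(seq_len(81), oracle_code[keep] + 1)] == 0))
  gof <- chisq.test(counts[oracle_code[keep] + 1], p = oracle$probs[keep])
  expect_gt(gof$p.value, 0.01)
})
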