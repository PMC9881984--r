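#' Simulation configuration for the two-population Balding-Nichols model
#'
#' Bundles and validates the parameters of the synthetic-data generator used
#' throughout the package: an "external" GWAS cohort plus a set of trio
#' families, drawn from two populations whose allele frequencies diverge
#' according to the Balding-Nichols model, with phenotypes confounded by the
#' population label.
#'
#' Defaults correspond to the reference simulation design: 50,000 external
#' samples, 1,000 trio families evenly split between two populations with
#' fixation index 0.01, 100 SNPs of which 50 are causal for the exposure, and
#' exposure heritability 0.2. Experiments at other scales pass the values
#' explicitly.
#'
#' @param n_external Number of unrelated external-cohort individuals.
#' @param n_families Number of trio families.
#' @param m_snps Number of SNPs (all independent).
#' @param m_causal Number of SNPs with a nonzero effect on the exposure.
#' @param fst Fixation index in `[0, 1)` governing between-population
#'   allele-frequency divergence. `fst = 0` collapses both populations onto
#'   the ancestral frequencies exactly.
#' @param h2 Heritability of the exposure trait in `[0, 1]`: the fraction of
#'   exposure variance explained by the causal SNPs when there is no
#'   confounding.
#' @param gamma_confound Effect of the binary population label on both the
#'   exposure and the outcome phenotype (the stratification confounder). Use
#'   `gamma_exposure`/`gamma_outcome` to set the two effects independently.
#' @param beta_causal_EO Causal effect of the exposure on the outcome. The
#'   null hypothesis of every test in this package is `beta_causal_EO = 0`.
#' @param pop_split Fraction of individuals assigned to population 1.
#' @param ancestral_freq_range Bounds, strictly inside (0, 1), for the uniform
#'   law of ancestral allele frequencies.
#' @param gamma_exposure,gamma_outcome Optional overrides of `gamma_confound`
#'   for the exposure and outcome separately.
#' @param seed Optional integer seed; when set, [simulate_mr_data()] produces
#'   a bit-identical dataset for the same configuration.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [simulate_mr_data()], [simulate_genotypes()],
#'   [simulate_phenotypes()]
#' @export
sim_config <- function(n_external = 50000, n_families = 1000, m_snps = 100,
                       m_causal = 50, fst = 0.01, h2 = 0.2,
                       gamma_confound = 0, beta_causal_EO = 0,
                       pop_split = 0.5,
                       ancestral_freq_range = c(0.05, 0.95),
                       gamma_exposure = NULL, gamma_outcome = NULL,
                       seed = NULL) {
  stopifnot(n_external >= 0, n_families >= 0, m_snps >= 1)
  if (fst < 0 || fst >= 1)
    stop("`fst` must lie in [0, 1)", call. = FALSE)
  if (h2 < 0 || h2 > 1)
    stop("`h2` must lie in [0, 1]", call. = FALSE)
  if (m_causal > m_snps)
    stop("`m_causal` cannot exceed `m_snps`", call. = FALSE)
  if (pop_split <= 0 || pop_split >= 1)
    stop("`pop_split` must lie strictly in (0, 1)", call. = FALSE)
  r <- ancestral_freq_range
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] >= r[2])
    stop("`ancestral_freq_range` must be an increasing pair strictly inside (0, 1)",
         call. = FALSE)
  if (abs(beta_causal_EO) > 1)
    stop("|beta_causal_EO| > 1 would require negative outcome noise variance ",
         "under unit phenotype scaling", call. = FALSE)
  cfg <- list(n_external = as.integer(n_external),
              n_families = as.integer(n_families),
              m_snps = as.integer(m_snps), m_causal = as.integer(m_causal),
              fst = fst, h2 = h2,
              gamma_exposure = if (is.null(gamma_exposure)) gamma_confound else gamma_exposure,
              gamma_outcome = if (is.null(gamma_outcome)) gamma_confound else gamma_outcome,
              beta_causal_EO = beta_causal_EO, pop_split = pop_split,
              ancestral_freq_range = as.numeric(r),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-population Balding-Nichols simulation config\n")
  cat(sprintf("  external n = %d, families = %d, SNPs = %d (%d causal)\n",
              x$n_external, x$n_families, x$m_snps, x$m_causal))
  cat(sprintf("  Fst = %g, h2 = %g, gamma (E, O) = (%g, %g), beta_EO = %g\n",
              x$fst, x$h2, x$gamma_exposure, x$gamma_outcome,
              x$beta_causal_EO))
  invisible(x)
}

## Population-specific allele frequencies under Balding-Nichols:
## p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F), mean p, variance F p(1-p).
## F = 0 is the degenerate branch: both populations share p exactly.
bn_pop_freqs <- function(p_anc, fst) {
  m <- length(p_anc)
  if (fst == 0) return(rbind(p_anc, p_anc, deparse.level = 0))
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  rbind(stats::rbeta(m, a, b), stats::rbeta(m, a, b), deparse.level = 0)
}

## Binomial(2, p) genotype draws for n individuals with population labels
## pop (0/1) and a 2 x m frequency matrix.
draw_genotypes <- function(pop, freqs) {
  n <- length(pop)
  m <- ncol(freqs)
  pr <- freqs[pop + 1L, , drop = FALSE]
  matrix(stats::rbinom(n * m, 2L, as.vector(pr)), n, m)
}

#' Simulate genotypes under the two-population Balding-Nichols model
#'
#' For each SNP an ancestral frequency is drawn uniformly from
#' `config$ancestral_freq_range`; the two population-specific frequencies are
#' then drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)` (mean `p`, variance
#' `F p (1-p)`), and each individual's genotype is `Binomial(2, p_k)` for
#' their population `k`. SNPs are independent. External individuals and the
#' trio parents are drawn from the same population-frequency realizations, so
#' the external cohort and the family data represent the same pair of
#' populations.
#'
#' @param config A [sim_config()] object.
#' @return A list with components `external` (`n_external x m_snps` integer
#'   matrix), `parent1` and `parent2` (`n_families x m_snps` matrices, one row
#'   per family), `pop_external` and `pop_families` (0/1 labels), `freqs`
#'   (2 x m population frequencies) and `p_anc`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  r <- config$ancestral_freq_range
  p_anc <- stats::runif(config$m_snps, r[1], r[2])
  freqs <- bn_pop_freqs(p_anc, config$fst)

  pop_ext <- as.integer(seq_len(config$n_external) >
                          round(config$n_external * config$pop_split))
  pop_fam <- as.integer(seq_len(config$n_families) >
                          round(config$n_families * config$pop_split))
  list(external = draw_genotypes(pop_ext, freqs),
       parent1 = draw_genotypes(pop_fam, freqs),
       parent2 = draw_genotypes(pop_fam, freqs),
       pop_external = pop_ext, pop_families = pop_fam,
       freqs = freqs, p_anc = p_anc)
}

#' Sample offspring genotypes from two parents by Mendelian inheritance
#'
#' Per SNP, the offspring genotype is `Bernoulli(P1/2) + Bernoulli(P2/2)`:
#' each parent transmits one allele, a homozygote transmits its allele with
#' certainty and a heterozygote transmits either allele with probability 1/2.
#' SNPs are treated as independent (no linkage), so no haplotype information
#' is needed. This is the same law used to generate digital twins in trio
#' mode ([sample_twin_trio()]).
#'
#' @param parent1,parent2 Genotype vectors or conformable matrices with
#'   entries in `{0, 1, 2}`.
#' @return Offspring genotypes with the same shape as the inputs.
#' @export
sample_offspring <- function(parent1, parent2) {
  check_geno(parent1, "parent1")
  check_geno(parent2, "parent2")
  stopifnot(length(parent1) == length(parent2))
  out <- stats::rbinom(length(parent1), 1L, as.vector(parent1) / 2) +
    stats::rbinom(length(parent2), 1L, as.vector(parent2) / 2)
  if (is.matrix(parent1)) dim(out) <- dim(parent1)
  out
}

check_geno <- function(g, label) {
  v <- as.vector(g)
  if (anyNA(v) || !all(v %in% c(0L, 1L, 2L)))
    stop("invalid genotype in `", label, "`: entries must be 0, 1, or 2",
         call. = FALSE)
  invisible(g)
}

#' Simulate exposure and outcome phenotypes with stratification confounding
#'
#' The exposure is `E = X beta_XE + gamma_E pop + e_E` where `beta_XE` is
#' nonzero only for the causal SNPs and is scaled so the genetic component
#' explains `h2` of the exposure variance when there is no confounding; the
#' outcome is `O = beta_EO E + gamma_O pop + e_O`. Noise terms are independent
#' Gaussians scaled so each phenotype has approximately unit variance at
#' `gamma = 0`; the population-label effects are added on top of that unit
#' scale, so `gamma` and `beta_causal_EO` are directly comparable across runs.
#'
#' @param genotypes `n x m` genotype matrix.
#' @param pop_labels 0/1 population label per individual.
#' @param config A [sim_config()] object.
#' @param beta_XE Optional per-SNP exposure effect vector (length `m`). When
#'   omitted, effects are drawn i.i.d. Gaussian for the first `m_causal` SNPs
#'   and rescaled against the realized genetic variance in `genotypes` to hit
#'   `h2`. Pass the returned `beta_XE` back in to phenotype a second cohort
#'   (e.g. trio offspring) under the identical genetic architecture.
#' @return A list with `exposure`, `outcome` (numeric vectors) and `beta_XE`.
#' @export
simulate_phenotypes <- function(genotypes, pop_labels, config, beta_XE = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  stopifnot(length(pop_labels) == n, m == config$m_snps)
  if (is.null(beta_XE)) {
    beta_XE <- numeric(m)
    if (config$m_causal > 0 && config$h2 > 0) {
      idx <- seq_len(config$m_causal)
      b <- stats::rnorm(config$m_causal)
      g <- as.vector(genotypes[, idx, drop = FALSE] %*% b)
      vg <- stats::var(g)
      if (vg > 0) beta_XE[idx] <- b * sqrt(config$h2 / vg)
    }
  } else {
    stopifnot(length(beta_XE) == m)
  }
  g <- as.vector(genotypes %*% beta_XE)
  e_var <- max(0, 1 - config$h2)
  exposure <- g + config$gamma_exposure * pop_labels +
    stats::rnorm(n, 0, sqrt(e_var))
  o_var <- 1 - config$beta_causal_EO^2
  if (o_var < 0)
    stop("negative outcome noise variance requested", call. = FALSE)
  outcome <- config$beta_causal_EO * exposure +
    config$gamma_outcome * pop_labels + stats::rnorm(n, 0, sqrt(o_var))
  list(exposure = exposure, outcome = outcome, beta_XE = beta_XE)
}

#' Simulate a complete external cohort plus trio family dataset
#'
#' Runs the full generative model: Balding-Nichols genotypes for an external
#' cohort and trio parents ([simulate_genotypes()]), Mendelian offspring
#' ([sample_offspring()]), and confounded linear phenotypes for both cohorts
#' under a shared genetic architecture ([simulate_phenotypes()]).
#'
#' @param config A [sim_config()] object. If `config$seed` is set, the RNG is
#'   seeded first and the result is bit-identical across calls.
#' @return A list of class `"sim_dataset"` with components:
#'   `external` (list: `genotypes`, `exposure`, `outcome`, `pop`),
#'   `families` (a trio [family_set()] carrying offspring genotypes, parents,
#'   offspring `exposure` and `outcome`, and family `pop` labels),
#'   `true_beta_XE` (per-SNP exposure effects), `snp_ids`, and `config`.
#' @export
simulate_mr_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  gen <- simulate_genotypes(config)
  snp_ids <- paste0("snp", seq_len(config$m_snps))
  colnames(gen$external) <- snp_ids

  ph_ext <- simulate_phenotypes(gen$external, gen$pop_external, config)
  offspring <- sample_offspring(gen$parent1, gen$parent2)
  ph_off <- simulate_phenotypes(offspring, gen$pop_families, config,
                                beta_XE = ph_ext$beta_XE)

  fam <- family_set(design = "trio", offspring = offspring,
                    parent1 = gen$parent1, parent2 = gen$parent2,
                    outcome = ph_off$outcome, exposure = ph_off$exposure,
                    snp_ids = snp_ids, pop = gen$pop_families)
  structure(list(external = list(genotypes = gen$external,
                                 exposure = ph_ext$exposure,
                                 outcome = ph_ext$outcome,
                                 pop = gen$pop_external),
                 families = fam,
                 true_beta_XE = ph_ext$beta_XE,
                 snp_ids = snp_ids,
                 config = config),
            class = "sim_dataset")
}
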