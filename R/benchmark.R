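#' Define a replicate-experiment grid
#'
#' Collects the settings of a false-positive-rate or power experiment:
#' how many simulation replicates, which confounding strengths and causal
#' effect sizes, which methods to run, and the simulation scale. Every
#' replicate draws its own seed deterministically from `seed`, so the whole
#' experiment is reproducible from `(grid, seed)`.
#'
#' @param n_reps Simulation replicates per grid cell.
#' @param gamma Confounding strengths (effect of the population label on
#'   both phenotypes) for the FPR experiment.
#' @param beta_EO Causal effect sizes for the power experiment.
#' @param methods Methods to run per replicate; any of `"mrtwin_trio"`,
#'   `"mrtwin_duo"`, `"mrtwin_sibling"`, `"ivw"`, `"egger"`, `"ratio"`.
#' @param B Digital twins per MR-Twin run (100 by default for replicate
#'   studies).
#' @param alpha Significance level for rejection counting.
#' @param bonferroni_alpha,f_threshold Instrument-selection thresholds
#'   (see [select_instruments()]); `bonferroni_alpha = Inf` runs the
#'   "unfiltered" mode.
#' @param use_trio_offspring If `TRUE`, the summary-statistic baselines
#'   (IVW/Egger/ratio) compute their GWAS on the trio offspring instead of
#'   the external cohort, so all methods see the same sample size; MR-Twin
#'   always uses the external summary statistics.
#' @param config A [sim_config()] giving the simulation scale; its
#'   `gamma_confound`/`beta_causal_EO`/`seed` fields are overridden per cell.
#' @param seed Master seed for the experiment.
#' @return An object of class `"experiment_grid"`.
#' @export
experiment_grid <- function(n_reps = 500,
                            gamma = c(0, 0.2, 0.4, 0.6, 0.8),
                            beta_EO = c(0, 0.05, 0.1, 0.2),
                            methods = c("mrtwin_trio", "ivw", "egger"),
                            B = 100, alpha = 0.05,
                            bonferroni_alpha = 0.05, f_threshold = NULL,
                            use_trio_offspring = FALSE,
                            config = sim_config(), seed = 1) {
  known <- c("mrtwin_trio", "mrtwin_duo", "mrtwin_sibling",
             "ivw", "egger", "ratio")
  bad <- setdiff(methods, known)
  if (length(bad) > 0)
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(inherits(config, "sim_config"), n_reps >= 1, B >= 1)
  structure(list(n_reps = as.integer(n_reps), gamma = gamma,
                 beta_EO = beta_EO, methods = methods, B = as.integer(B),
                 alpha = alpha, bonferroni_alpha = bonferroni_alpha,
                 f_threshold = f_threshold,
                 use_trio_offspring = use_trio_offspring,
                 config = config, seed = as.integer(seed)),
            class = "experiment_grid")
}

## Build a sibling family_set from a trio dataset: the proband keeps their
## outcome, and one extra sibling is drawn from the same parents.
trio_to_sibling <- function(fam) {
  sib2 <- sample_offspring(fam$parent1, fam$parent2)
  sibs <- lapply(seq_len(nrow(fam$offspring)), function(n)
    rbind(fam$offspring[n, ], sib2[n, ]))
  family_set(design = "sibling", siblings = sibs, outcome = fam$outcome,
             snp_ids = fam$snp_ids)
}

trio_to_duo <- function(fam) {
  family_set(design = "duo", offspring = fam$offspring,
             parent1 = fam$parent1, outcome = fam$outcome,
             snp_ids = fam$snp_ids)
}

## One simulation replicate: returns a named vector of p-values (NA where a
## method could not run, e.g. no instruments or ratio with J > 1).
one_replicate <- function(cfg, grid, rep_seed) {
  set.seed(rep_seed)
  dat <- simulate_mr_data(cfg)
  p <- stats::setNames(rep(NA_real_, length(grid$methods)), grid$methods)

  ss_ext <- suppressWarnings(
    gwas_summary_stats(dat$external$genotypes, dat$external$exposure,
                       dat$external$outcome))
  ss_base <- ss_ext
  if (grid$use_trio_offspring) {
    g_off <- dat$families$offspring
    colnames(g_off) <- dat$snp_ids
    ss_base <- suppressWarnings(
      gwas_summary_stats(g_off, dat$families$exposure,
                         dat$families$outcome))
  }

  run_baseline <- function(ss, method) {
    inst <- select_instruments(ss, m = cfg$m_snps,
                               bonferroni_alpha = grid$bonferroni_alpha,
                               f_threshold = grid$f_threshold)
    if (length(inst) == 0) return(NA_real_)
    st <- ss[match(inst, ss$snp_id), , drop = FALSE]
    if (method == "ratio" && nrow(st) != 1) return(NA_real_)
    if (method == "egger" && nrow(st) < 3) return(NA_real_)
    mr_estimate(st, method)$p_value
  }
  for (method in intersect(grid$methods, c("ivw", "egger", "ratio")))
    p[method] <- tryCatch(run_baseline(ss_base, method),
                          error = function(e) NA_real_)

  run_twin <- function(fam, sibling_method = "pool") {
    tryCatch(
      mrtwin(fam, ss_ext, B = grid$B,
             bonferroni_alpha = grid$bonferroni_alpha,
             f_threshold = grid$f_threshold,
             sibling_method = sibling_method)$p_value,
      mrtwin_no_instruments = function(e) NA_real_,
      error = function(e) NA_real_)
  }
  if ("mrtwin_trio" %in% grid$methods)
    p["mrtwin_trio"] <- run_twin(dat$families)
  if ("mrtwin_duo" %in% grid$methods)
    p["mrtwin_duo"] <- run_twin(trio_to_duo(dat$families))
  if ("mrtwin_sibling" %in% grid$methods)
    p["mrtwin_sibling"] <- run_twin(trio_to_sibling(dat$families))
  p
}

run_cells <- function(grid, cells, label) {
  set.seed(grid$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             grid$n_reps * length(cells)),
                  nrow = grid$n_reps)
  rows <- list()
  p_values <- list()
  for (ci in seq_along(cells)) {
    cfg <- cells[[ci]]
    pmat <- vapply(seq_len(grid$n_reps), function(r)
      one_replicate(cfg, grid, seeds[r, ci]),
      numeric(length(grid$methods)))
    pmat <- matrix(pmat, nrow = length(grid$methods),
                   dimnames = list(grid$methods, NULL))
    p_values[[as.character(attr(cfg, "cell_value"))]] <- pmat
    for (method in grid$methods) {
      pv <- pmat[method, ]
      ok <- !is.na(pv)
      k <- sum(pv[ok] < grid$alpha)
      n <- sum(ok)
      ci95 <- if (n > 0) stats::binom.test(k, n)$conf.int else c(NA, NA)
      rows[[length(rows) + 1]] <- data.frame(
        method = method,
        value = attr(cfg, "cell_value"),
        rejection_rate = if (n > 0) k / n else NA_real_,
        ci_lower = ci95[1], ci_upper = ci95[2],
        n_ok = n, n_failed = grid$n_reps - n,
        flagged = (grid$n_reps - n) / grid$n_reps > 0.05,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "value"] <- label
  ## raw per-replicate p-values (methods x reps, one matrix per cell) for
  ## calibration diagnostics beyond the rejection rate
  attr(out, "p_values") <- p_values
  out
}

cell_config <- function(base, gamma = NULL, beta_EO = NULL, value) {
  cfg <- base
  if (!is.null(gamma)) {
    cfg$gamma_exposure <- gamma
    cfg$gamma_outcome <- gamma
  }
  if (!is.null(beta_EO)) cfg$beta_causal_EO <- beta_EO
  cfg$seed <- NULL
  attr(cfg, "cell_value") <- value
  cfg
}

#' Run the false-positive-rate experiment
#'
#' For each confounding strength in `grid$gamma`, simulates `n_reps`
#' datasets under the causal null (`beta_causal_EO = 0`), runs every method,
#' and tabulates the fraction of replicates rejected at `grid$alpha` with an
#' exact binomial 95% confidence interval. Replicates where a method could
#' not run (e.g. no instruments passed selection) are excluded from that
#' cell's denominator and counted in `n_failed`; a cell is `flagged` when
#' more than 5% of its replicates failed.
#'
#' @param grid An [experiment_grid()].
#' @return A data frame with one row per (method, gamma) cell. The raw
#'   per-replicate p-values are attached as `attr(, "p_values")`, a list of
#'   method-by-replicate matrices keyed by cell value.
#' @export
run_fpr_experiment <- function(grid) {
  stopifnot(inherits(grid, "experiment_grid"))
  cells <- lapply(grid$gamma, function(g)
    cell_config(grid$config, gamma = g, beta_EO = 0, value = g))
  run_cells(grid, cells, "gamma")
}

#' Run the power experiment
#'
#' For each causal effect size in `grid$beta_EO`, simulates `n_reps`
#' datasets with no confounding (`gamma = 0`) and tabulates rejection rates
#' as in [run_fpr_experiment()].
#'
#' @param grid An [experiment_grid()].
#' @return A data frame with one row per (method, beta_EO) cell.
#' @export
run_power_experiment <- function(grid) {
  stopifnot(inherits(grid, "experiment_grid"))
  cells <- lapply(grid$beta_EO, function(b)
    cell_config(grid$config, gamma = 0, beta_EO = b, value = b))
  run_cells(grid, cells, "beta_EO")
}

#' P-value stability as a function of the number of digital twins
#'
#' Re-runs the MR-Twin test on one fixed dataset many times, varying only
#' the twin randomization, for each candidate `B`, and reports the standard
#' deviation of the resulting p-values. The dispersion shrinks as `B` grows
#' (at rate `sqrt(p(1-p)/B)`), which is what makes ~100 twins adequate for
#' replicate studies but ~1000 preferable for a one-off analysis.
#'
#' @param families A [family_set()] with outcomes.
#' @param stats External summary statistics.
#' @param B_values Candidate twin counts.
#' @param n_runs Re-runs per `B`.
#' @param seed Master seed.
#' @param ... Passed to [mrtwin()] (e.g. `instruments`, `estimator`).
#' @return A data frame with columns `B`, `mean_p`, `sd_p`, `n_runs`.
#' @export
run_stability_experiment <- function(families, stats,
                                     B_values = c(25, 100, 1000),
                                     n_runs = 50, seed = 1, ...) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             n_runs * length(B_values)),
                  nrow = n_runs)
  rows <- lapply(seq_along(B_values), function(bi) {
    ps <- vapply(seq_len(n_runs), function(r)
      mrtwin(families, stats, B = B_values[bi], seed = seeds[r, bi],
             ...)$p_value, 0)
    data.frame(B = B_values[bi], mean_p = mean(ps), sd_p = stats::sd(ps),
               n_runs = n_runs)
  })
  do.call(rbind, rows)
}
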