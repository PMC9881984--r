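#' Genetically-predicted-outcome test statistic
#'
#' The statistic underlying the digital-twin test: each individual's
#' exposure is predicted from their instrument genotypes with the external
#' per-SNP effect sizes, `E_hat_n = sum_j beta_XE_j X_nj`; the outcome is
#' then predicted as `O_hat_n = beta_EO * E_hat_n`; and the statistic is the
#' negative squared prediction error
#' `t = -sum_n (O_hat_n - O_n)^2`.
#' Larger `t` means the genotypes predict the outcome better. Both
#' `beta_XE` and `beta_EO` come from external summary data and are held
#' fixed across the true offspring and every twin replicate.
#'
#' @param genotypes `N x M` genotype matrix over the instrument SNPs.
#' @param outcomes Numeric outcome vector of length `N`.
#' @param beta_XE Per-SNP exposure effect sizes, aligned with the genotype
#'   columns (named vectors/column names are checked when both present).
#' @param beta_EO Scalar exposure-on-outcome estimate, or an
#'   `"mr_estimate"`.
#' @return The scalar statistic `t`.
#' @export
mrtwin_statistic <- function(genotypes, outcomes, beta_XE, beta_EO) {
  genotypes <- as.matrix(genotypes)
  if (inherits(beta_EO, "mr_estimate")) beta_EO <- beta_EO$beta_EO
  if (length(beta_XE) != ncol(genotypes))
    stop("`beta_XE` is not aligned with the genotype columns (",
         length(beta_XE), " effects vs ", ncol(genotypes), " SNPs)",
         call. = FALSE)
  if (!is.null(names(beta_XE)) && !is.null(colnames(genotypes)) &&
      !identical(names(beta_XE), colnames(genotypes)))
    stop("`beta_XE` names do not match genotype column names", call. = FALSE)
  if (length(outcomes) != nrow(genotypes))
    stop("`outcomes` length does not match the genotype rows", call. = FALSE)
  if (any(!is.finite(outcomes)))
    stop("non-finite outcome value", call. = FALSE)
  e_hat <- as.vector(genotypes %*% beta_XE)
  -sum((beta_EO * e_hat - outcomes)^2)
}

#' MR-Twin: a digital-twin conditional randomization test for a causal effect
#'
#' Tests the null hypothesis that the exposure has no causal effect on the
#' outcome, using external GWAS summary statistics for the per-SNP weights
#' and family genotype data for the randomization. The test
#' \enumerate{
#'   \item estimates `beta_EO` once from the external summary statistics
#'     (IVW by default);
#'   \item computes the prediction statistic [mrtwin_statistic()] on the true
#'     offspring, `t*`;
#'   \item draws `B` digital-twin genotype replicates conditionally on the
#'     family data (trio, duo, or sibling design) and computes the same
#'     statistic `t_b` for each, holding the outcome values and all external
#'     estimates fixed;
#'   \item returns `p = (1 + #\{b : t_b >= t*\}) / (1 + B)`.
#' }
#' Because offspring genotypes are independent of population structure (and
#' of any other confounder acting through the parents, such as assortative
#' mating or dynastic effects) given the parental genotypes, the twins are
#' exchangeable with the true offspring under the null, and the p-value is
#' valid no matter how confounded the external summary statistics are. The
#' smallest attainable p-value is `1/(B + 1)`, and every p-value lies on the
#' grid `k/(B + 1)`.
#'
#' Ties between `t_b` and `t*` count toward the null (the conservative
#' randomization-test convention), so a degenerate statistic — e.g.
#' `beta_EO = 0`, which makes the statistic identical for offspring and
#' twins — yields `p = 1`.
#'
#' @param families A [family_set()] (trio, duo, or sibling design) carrying
#'   outcome values.
#' @param stats External summary statistics (`mr_summary_stats` data frame).
#' @param instruments Character vector of instrument SNP ids. Default
#'   `NULL` selects them from `stats` via [select_instruments()].
#' @param B Number of digital twins. Use 1000 or more for a one-off real
#'   data analysis; 100 is adequate inside large simulation studies.
#' @param estimator Method for `beta_EO`: `"ivw"` (default), `"egger"`, or
#'   `"ratio"` (single instrument only).
#' @param bonferroni_alpha,f_threshold Passed to [select_instruments()] when
#'   `instruments` is `NULL`.
#' @param seed Optional integer seed; fixes the twin randomization.
#' @param two_sided If `TRUE`, also reject when the true offspring predict
#'   the outcome markedly *worse* than their twins
#'   (`p = 2 min(P(t_b >= t*), P(t_b <= t*))`, capped at 1). The standard
#'   test is one-sided (`FALSE`): a causal effect makes the true offspring's
#'   genetic prediction better, not worse.
#' @param sibling_method Sibling resampling rule, see [twin_samplers].
#' @param chunk_size Twin replicates per internal chunk (memory knob; the
#'   result is chunk-invariant given the seed).
#' @return An object of class `"mrtwin"`: list with `p_value`, `t_star`,
#'   `t_null` (length `B`), `B`, `estimate` (the `"mr_estimate"` used),
#'   `design`, `n_families`, `instruments`, `dropped_snps`, `seed`.
#' @examples
#' cfg <- sim_config(n_external = 2000, n_families = 100, m_snps = 20,
#'                   m_causal = 10, beta_causal_EO = 0, gamma_confound = 0.8,
#'                   seed = 1)
#' dat <- simulate_mr_data(cfg)
#' ss <- gwas_summary_stats(dat$external$genotypes, dat$external$exposure,
#'                          dat$external$outcome)
#' mrtwin(dat$families, ss, B = 99, seed = 2)
#' @export
mrtwin <- function(families, stats, instruments = NULL, B = 1000,
                   estimator = c("ivw", "egger", "ratio"),
                   bonferroni_alpha = 0.05, f_threshold = NULL,
                   seed = NULL, two_sided = FALSE,
                   sibling_method = c("pool", "pairs"), chunk_size = NULL) {
  stopifnot(inherits(families, "family_set"), B >= 1)
  estimator <- match.arg(estimator)
  sibling_method <- match.arg(sibling_method)
  validate_summary_stats(stats)

  if (is.null(instruments))
    instruments <- select_instruments(stats, m = nrow(stats),
                                      bonferroni_alpha = bonferroni_alpha,
                                      f_threshold = f_threshold)
  if (length(instruments) == 0) no_instruments_error()

  ## align: instruments must exist in both the stats and the family SNPs
  missing_in_fam <- setdiff(instruments, families$snp_ids)
  if (length(missing_in_fam) > 0)
    stop("instrument(s) absent from the family genotypes: ",
         paste(utils::head(missing_in_fam, 5), collapse = ", "),
         call. = FALSE)
  keep <- match(instruments, families$snp_ids)
  fam <- subset_snps(families, keep)

  ## SNPs with recorded Mendelian inconsistencies are dropped family-wise
  dropped <- character(0)
  if (!is.null(families$mendel_errors)) {
    bad_cols <- unique(families$mendel_errors[, "col"])
    bad_ids <- families$snp_ids[bad_cols]
    dropped <- intersect(instruments, bad_ids)
    if (length(dropped) > 0) {
      fam <- subset_snps(fam, !(fam$snp_ids %in% dropped))
      instruments <- setdiff(instruments, dropped)
      if (length(instruments) == 0) no_instruments_error()
    }
  }

  st <- stats[match(instruments, stats$snp_id), , drop = FALSE]
  if (anyNA(st$snp_id))
    stop("instrument(s) absent from the summary statistics", call. = FALSE)
  if (is.null(fam$outcome))
    stop("`families` carries no outcome values", call. = FALSE)

  est <- mr_estimate(st, estimator)
  beta_xe <- st$beta_exposure
  o <- fam$outcome

  t_star <- mrtwin_statistic(fam$offspring, o, beta_xe, est$beta_EO)

  if (!is.null(seed)) set.seed(seed)
  n <- nrow(fam$offspring)
  m <- ncol(fam$offspring)
  if (is.null(chunk_size)) chunk_size <- max(1L, floor(5e6 / (2 * n * m)))
  t_null <- numeric(B)
  done <- 0L
  while (done < B) {
    r <- min(chunk_size, B - done)
    twins <- twin_chunk(fam, r, sibling_method)
    e_hat <- as.vector(twins %*% beta_xe)
    resid <- matrix(est$beta_EO * e_hat, n, r) - o
    t_null[done + seq_len(r)] <- -colSums(resid^2)
    done <- done + r
  }

  p_ge <- (1 + sum(t_null >= t_star)) / (1 + B)
  p <- if (two_sided) {
    p_le <- (1 + sum(t_null <= t_star)) / (1 + B)
    min(1, 2 * min(p_ge, p_le))
  } else p_ge

  structure(list(p_value = p, t_star = t_star, t_null = t_null, B = B,
                 estimate = est, design = families$design,
                 n_families = n, instruments = instruments,
                 dropped_snps = dropped, two_sided = two_sided,
                 seed = seed),
            class = "mrtwin")
}

#' @export
print.mrtwin <- function(x, ...) {
  cat(sprintf("MR-Twin conditional randomization test (%s design)\n",
              x$design))
  cat(sprintf("  %d families, %d instruments, B = %d digital twins\n",
              x$n_families, length(x$instruments), x$B))
  cat(sprintf("  beta_EO (%s) = %.4g\n", x$estimate$method,
              x$estimate$beta_EO))
  cat(sprintf("  t* = %.6g\n", x$t_star))
  cat(sprintf("  p-value = %.4g%s (minimum attainable %.3g)\n", x$p_value,
              if (x$two_sided) " [two-sided]" else "", 1 / (x$B + 1)))
  invisible(x)
}

#' @export
summary.mrtwin <- function(object, ...) {
  r <- rank(c(object$t_star, object$t_null))[1]
  out <- list(p_value = object$p_value, t_star = object$t_star,
              t_null_quantiles = stats::quantile(object$t_null),
              t_star_rank = r, B = object$B, design = object$design,
              n_families = object$n_families,
              n_instruments = length(object$instruments),
              estimate = object$estimate)
  class(out) <- "summary.mrtwin"
  out
}

#' @export
print.summary.mrtwin <- function(x, ...) {
  cat(sprintf("MR-Twin test: p = %.4g (%s design, %d families, B = %d)\n",
              x$p_value, x$design, x$n_families, x$B))
  cat(sprintf("  t* = %.6g, rank %.1f of %d among twin statistics\n",
              x$t_star, x$t_star_rank, x$B + 1))
  cat("  twin-statistic quantiles:\n")
  print(x$t_null_quantiles)
  cat(sprintf("  external estimate: beta_EO = %.4g (%s, %d instruments)\n",
              x$estimate$beta_EO, x$estimate$method, x$n_instruments))
  invisible(x)
}

#' Plot the twin null distribution against the observed statistic
#'
#' Histogram of the `B` digital-twin statistics with the true-offspring
#' statistic `t*` marked; the p-value is the (tie-inclusive) fraction of
#' twins at or above the line.
#'
#' @param x An `"mrtwin"` object.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.mrtwin <- function(x, ...) {
  graphics::hist(x$t_null, main = "MR-Twin null distribution",
                 xlab = "twin statistic t_b",
                 xlim = range(c(x$t_null, x$t_star)), ...)
  graphics::abline(v = x$t_star, col = "red", lwd = 2)
  graphics::mtext(sprintf("t* (p = %.3g)", x$p_value), col = "red",
                  side = 3, adj = 1)
  invisible(x)
}
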