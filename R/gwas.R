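#' Per-SNP marginal association scan
#'
#' Fits, for every SNP, the simple linear regression of a phenotype on the
#' additive genotype dosage (with intercept) and returns the slope, its
#' standard error, and the two-sided t-test p-value. Computed in closed form
#' from sufficient statistics, so the scan is a single pass over the matrix.
#'
#' Monomorphic SNPs (zero genotype variance) cannot be tested; they are
#' excluded from the result with a warning naming how many were dropped.
#'
#' @param genotypes `n x m` additive genotype matrix; column names are used
#'   as SNP ids when present.
#' @param phenotype Numeric phenotype vector of length `n`.
#' @return A data frame with columns `snp_id`, `beta`, `se`, `p`, `n`.
#' @export
marginal_gwas <- function(genotypes, phenotype) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  y <- as.numeric(phenotype)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 individuals for a marginal scan", call. = FALSE)
  if (any(!is.finite(y))) stop("non-finite phenotype value", call. = FALSE)

  snp_id <- colnames(genotypes)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(ncol(genotypes)))

  sx <- colSums(genotypes)
  sxx <- colSums(genotypes^2)
  Sxx <- sxx - sx^2 / n
  Sxy <- as.vector(crossprod(genotypes, y)) - sx * sum(y) / n
  Syy <- sum(y^2) - sum(y)^2 / n

  mono <- Sxx <= 0
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) excluded from the scan: ",
            paste(utils::head(snp_id[mono], 5), collapse = ", "),
            if (sum(mono) > 5) ", ..." else "", call. = FALSE)
  }
  beta <- ifelse(mono, NA_real_, Sxy / Sxx)
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- sqrt(rss / ((n - 2) * Sxx))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  out <- data.frame(snp_id = snp_id, beta = beta, se = se, p = p, n = n,
                    stringsAsFactors = FALSE)
  out[!mono, , drop = FALSE]
}

#' External GWAS summary statistics for exposure and outcome
#'
#' Runs [marginal_gwas()] against both phenotypes of an external cohort and
#' assembles the per-SNP summary-statistic table consumed by the MR
#' estimators and the digital-twin test: effect size, standard error and
#' p-value of each SNP on the exposure, and effect size with standard error
#' on the outcome.
#'
#' @param genotypes External-cohort genotype matrix.
#' @param exposure,outcome Phenotype vectors.
#' @return A data frame of class `"mr_summary_stats"` with columns `snp_id`,
#'   `beta_exposure`, `se_exposure`, `p_exposure`, `beta_outcome`,
#'   `se_outcome`, `p_outcome`, `n`.
#' @export
gwas_summary_stats <- function(genotypes, exposure, outcome) {
  ge <- marginal_gwas(genotypes, exposure)
  go <- marginal_gwas(genotypes, outcome)
  keep <- intersect(ge$snp_id, go$snp_id)
  ge <- ge[match(keep, ge$snp_id), ]
  go <- go[match(keep, go$snp_id), ]
  out <- data.frame(snp_id = keep,
                    beta_exposure = ge$beta, se_exposure = ge$se,
                    p_exposure = ge$p,
                    beta_outcome = go$beta, se_outcome = go$se,
                    p_outcome = go$p, n = ge$n,
                    stringsAsFactors = FALSE)
  class(out) <- c("mr_summary_stats", "data.frame")
  out
}

#' Select genetic instruments from summary statistics
#'
#' Retains SNPs whose exposure association passes the Bonferroni threshold
#' `p < bonferroni_alpha / m` and, when `f_threshold` is given, whose
#' single-regressor F-statistic `F = (beta/se)^2` meets it (the conventional
#' weak-instrument screen, `F >= 10`). Selection is a deterministic function
#' of the statistics and thresholds.
#'
#' @param stats An `mr_summary_stats` data frame (see [gwas_summary_stats()]
#'   or [read_summary_stats()]).
#' @param m Number of tests for the Bonferroni correction; defaults to the
#'   number of SNPs in `stats`.
#' @param bonferroni_alpha Family-wise error target (default 0.05). Set to
#'   `Inf` to disable the p-value filter ("unfiltered" mode).
#' @param f_threshold Optional minimum per-SNP F-statistic; `NULL` disables
#'   the weak-instrument filter.
#' @return Character vector of selected `snp_id`s.
#' @export
select_instruments <- function(stats, m = nrow(stats), bonferroni_alpha = 0.05,
                               f_threshold = NULL) {
  validate_summary_stats(stats)
  keep <- if (is.finite(bonferroni_alpha))
    stats$p_exposure < bonferroni_alpha / m
  else rep(TRUE, nrow(stats))
  if (!is.null(f_threshold)) {
    fstat <- (stats$beta_exposure / stats$se_exposure)^2
    keep <- keep & fstat >= f_threshold
  }
  stats$snp_id[keep]
}

no_instruments_error <- function() {
  stop(structure(class = c("mrtwin_no_instruments", "error", "condition"),
                 list(message = paste0(
                   "no instruments pass the selection thresholds; ",
                   "the test refuses to run"),
                   call = NULL)))
}

validate_summary_stats <- function(stats) {
  required <- c("snp_id", "beta_exposure", "se_exposure", "p_exposure",
                "beta_outcome", "se_outcome")
  missing_cols <- setdiff(required, names(stats))
  if (length(missing_cols) > 0)
    stop("summary statistics lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("se_exposure", "se_outcome"))
    if (any(stats[[col]] <= 0, na.rm = TRUE))
      stop("non-positive standard error in `", col, "`", call. = FALSE)
  if (any(stats$p_exposure < 0 | stats$p_exposure > 1, na.rm = TRUE))
    stop("`p_exposure` outside [0, 1]", call. = FALSE)
  invisible(stats)
}
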