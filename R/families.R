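#' Construct a family genotype set for trio, duo, or sibling designs
#'
#' A `family_set` holds, for N families at M SNPs, the genotype data needed to
#' generate digital twins plus the offspring outcome values:
#' \describe{
#'   \item{trio}{offspring plus both parents (`parent1`, `parent2`).}
#'   \item{duo}{offspring plus one observed parent (`parent1`).}
#'   \item{sibling}{two or more genotyped siblings per family, no parents;
#'     the first sibling of each family is the analyzed individual whose
#'     outcome is tested, and its genotypes form the `offspring` matrix.}
#' }
#' All genotype matrices are additive-coded (0/1/2) with one row per family
#' and a shared SNP order. Offspring are checked for Mendelian consistency
#' with the available parents: at each SNP the offspring dosage must lie
#' between the minimum and maximum transmissible dosage given the parental
#' genotypes (e.g. parents (0, 0) force offspring 0). Inconsistencies are a
#' hard error unless `allow_mendel_errors = TRUE`, in which case the
#' offending family/SNP cells are recorded in the `mendel_errors` attribute
#' and excluded SNP-wise from downstream statistics.
#'
#' @param design One of `"trio"`, `"duo"`, `"sibling"`.
#' @param offspring `N x M` offspring genotype matrix (trio/duo). For the
#'   sibling design this may be omitted; it defaults to the first sibling.
#' @param parent1,parent2 Parental genotype matrices (`parent2` trio only).
#' @param siblings For the sibling design, a list of length N whose n-th
#'   element is an `S_n x M` matrix of sibling genotypes (`S_n >= 2`), or a
#'   3-d array `N x S x M` for constant sibship size.
#' @param outcome Numeric outcome value per family's analyzed offspring.
#' @param exposure Optional exposure value per offspring (not used by the
#'   test; carried for benchmarking).
#' @param snp_ids Character vector of SNP identifiers (defaults to column
#'   names or `snp1..snpM`).
#' @param family_ids Optional family identifiers.
#' @param pop Optional population labels (simulation bookkeeping).
#' @param allow_mendel_errors Downgrade Mendelian inconsistencies from an
#'   error to per-cell exclusion with a message.
#' @return An object of class `"family_set"`.
#' @export
family_set <- function(design = c("trio", "duo", "sibling"),
                       offspring = NULL, parent1 = NULL, parent2 = NULL,
                       siblings = NULL, outcome = NULL, exposure = NULL,
                       snp_ids = NULL, family_ids = NULL, pop = NULL,
                       allow_mendel_errors = FALSE) {
  design <- match.arg(design)
  as_geno_matrix <- function(x, label) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    storage.mode(x) <- "integer"
    check_geno(x, label)
    x
  }
  offspring <- as_geno_matrix(offspring, "offspring")
  parent1 <- as_geno_matrix(parent1, "parent1")
  parent2 <- as_geno_matrix(parent2, "parent2")

  if (design == "sibling") {
    if (is.null(siblings)) stop("sibling design requires `siblings`", call. = FALSE)
    if (is.array(siblings) && length(dim(siblings)) == 3) {
      siblings <- lapply(seq_len(dim(siblings)[1]), function(n) {
        m <- siblings[n, , , drop = TRUE]
        if (is.null(dim(m))) m <- matrix(m, nrow = dim(siblings)[2])
        m
      })
    }
    siblings <- lapply(seq_along(siblings), function(n)
      as_geno_matrix(siblings[[n]], paste0("siblings[[", n, "]]")))
    ns <- vapply(siblings, nrow, 0L)
    if (any(ns < 2))
      stop("sibling design requires >= 2 genotyped siblings per family",
           call. = FALSE)
    mm <- unique(vapply(siblings, ncol, 0L))
    if (length(mm) != 1) stop("siblings disagree on SNP count", call. = FALSE)
    if (is.null(offspring))
      offspring <- do.call(rbind, lapply(siblings, function(s) s[1, ]))
  } else if (design == "trio") {
    if (is.null(offspring) || is.null(parent1) || is.null(parent2))
      stop("trio design requires `offspring`, `parent1`, and `parent2`",
           call. = FALSE)
  } else {
    if (is.null(offspring) || is.null(parent1))
      stop("duo design requires `offspring` and the observed `parent1`",
           call. = FALSE)
    if (!is.null(parent2))
      stop("duo design takes a single observed parent; pass it as `parent1`",
           call. = FALSE)
  }

  n <- nrow(offspring)
  m <- ncol(offspring)
  for (nm in c("parent1", "parent2")) {
    p <- get(nm)
    if (!is.null(p) && !identical(dim(p), c(n, m)))
      stop("`", nm, "` dimensions do not match `offspring`", call. = FALSE)
  }
  if (is.null(snp_ids)) snp_ids <- colnames(offspring)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  if (length(snp_ids) != m) stop("`snp_ids` length mismatch", call. = FALSE)
  if (is.null(family_ids)) family_ids <- paste0("fam", seq_len(n))
  if (!is.null(outcome)) {
    outcome <- as.numeric(outcome)
    if (length(outcome) != n)
      stop("`outcome` must have one value per family", call. = FALSE)
    if (any(!is.finite(outcome)))
      stop("non-finite outcome value", call. = FALSE)
  }

  fs <- structure(list(design = design, offspring = offspring,
                       parent1 = parent1, parent2 = parent2,
                       siblings = if (design == "sibling") siblings else NULL,
                       outcome = outcome, exposure = exposure,
                       snp_ids = snp_ids, family_ids = family_ids, pop = pop,
                       mendel_errors = NULL),
                  class = "family_set")
  bad <- mendel_violations(fs)
  if (any(bad)) {
    if (!allow_mendel_errors)
      stop(sum(bad), " Mendelian-inconsistent offspring genotype cell(s); ",
           "use allow_mendel_errors = TRUE to exclude them per SNP",
           call. = FALSE)
    message("excluding ", sum(bad),
            " Mendelian-inconsistent genotype cell(s) family-wise")
    fs$mendel_errors <- which(bad, arr.ind = TRUE)
  }
  fs
}

## Logical N x M matrix: TRUE where the offspring dosage cannot arise from
## the recorded parents. Transmissible range per parent: {1} if hom-alt,
## {0} if hom-ref, {0,1} if het; duo bounds use the single observed parent.
mendel_violations <- function(fs) {
  x <- fs$offspring
  if (fs$design == "trio") {
    lo <- (fs$parent1 == 2L) + (fs$parent2 == 2L)
    hi <- (fs$parent1 > 0L) + (fs$parent2 > 0L)
  } else if (fs$design == "duo") {
    lo <- (fs$parent1 == 2L) + 0L
    hi <- (fs$parent1 > 0L) + 1L
  } else {
    return(matrix(FALSE, nrow(x), ncol(x)))
  }
  x < lo | x > hi
}

#' @export
print.family_set <- function(x, ...) {
  cat(sprintf("family_set: %d %s families x %d SNPs\n",
              nrow(x$offspring), x$design, ncol(x$offspring)))
  if (x$design == "sibling") {
    ns <- vapply(x$siblings, nrow, 0L)
    cat(sprintf("  sibship sizes: %s\n",
                paste(range(ns), collapse = "-")))
  }
  cat(sprintf("  outcome: %s\n",
              if (is.null(x$outcome)) "absent" else "present"))
  if (!is.null(x$mendel_errors))
    cat(sprintf("  %d Mendelian-inconsistent cells excluded\n",
                nrow(x$mendel_errors)))
  invisible(x)
}

#' Number of families in a family set
#' @param fs A [family_set()].
#' @return Integer count.
#' @export
n_families <- function(fs) {
  stopifnot(inherits(fs, "family_set"))
  nrow(fs$offspring)
}

## Subset a family_set to SNP columns `keep` (logical or index), preserving
## design-specific components.
subset_snps <- function(fs, keep) {
  fs$offspring <- fs$offspring[, keep, drop = FALSE]
  for (nm in c("parent1", "parent2"))
    if (!is.null(fs[[nm]])) fs[[nm]] <- fs[[nm]][, keep, drop = FALSE]
  if (!is.null(fs$siblings))
    fs$siblings <- lapply(fs$siblings, function(s) s[, keep, drop = FALSE])
  fs$snp_ids <- fs$snp_ids[keep]
  fs
}
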