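#' Digital-twin genotype samplers
#'
#' A digital twin is a synthetic offspring genotype drawn from its family's
#' genotype data so that, conditional on that data, the twin has the same
#' distribution as the true offspring. Instrument SNPs are assumed
#' independent, so haplotype-level inheritance reduces to independent
#' per-SNP allele draws and no phasing is required.
#'
#' \describe{
#'   \item{trio}{`D_j = Bernoulli(P1_j/2) + Bernoulli(P2_j/2)` — each parent
#'     transmits one allele; identical in law to [sample_offspring()].}
#'   \item{duo}{the allele from the unobserved parent is fixed at its value
#'     in the true offspring; the observed parent's allele is resampled.
#'     If the observed parent is homozygous the twin equals the offspring at
#'     that SNP; if heterozygous, `D_j = Bernoulli(1/2) + Bernoulli(X_j/2)`.}
#'   \item{sibling}{the twin's two alleles are drawn independently and
#'     uniformly from the `2S` pooled alleles of the `S` observed siblings at
#'     that SNP, i.e. `D_j ~ Binomial(2, s_j / 2S)` where `s_j` is the pooled
#'     alternate-allele count (the "shuffling" approximation). The
#'     alternative `method = "pairs"` instead picks two distinct siblings at
#'     random and draws one allele from each.}
#' }
#'
#' @param parent1,parent2 Parental genotype vectors (entries 0/1/2).
#' @param offspring True offspring genotype vector (duo mode).
#' @param siblings `S x M` matrix of sibling genotypes, `S >= 2`.
#' @param method Sibling resampling rule: `"pool"` (default) or `"pairs"`.
#' @return A twin genotype vector with entries in `{0, 1, 2}`.
#' @seealso [generate_twin_batch()] for batch generation over a
#'   [family_set()].
#' @name twin_samplers
NULL

#' @rdname twin_samplers
#' @export
sample_twin_trio <- function(parent1, parent2) {
  sample_offspring(parent1, parent2)
}

#' @rdname twin_samplers
#' @export
sample_twin_duo <- function(parent1, offspring) {
  check_geno(parent1, "parent1")
  if (is.null(offspring))
    stop("duo mode requires the offspring genotype", call. = FALSE)
  check_geno(offspring, "offspring")
  stopifnot(length(parent1) == length(offspring))
  pr <- duo_allele_probs(as.vector(parent1), as.vector(offspring))
  out <- stats::rbinom(length(pr$a), 1L, pr$a) +
    stats::rbinom(length(pr$b), 1L, pr$b)
  if (is.matrix(parent1)) dim(out) <- dim(parent1)
  out
}

## Per-SNP Bernoulli probabilities (a = observed parent's allele,
## b = the fixed allele from the unobserved parent). For a homozygous
## observed parent both draws are degenerate and reproduce the offspring;
## for a heterozygote, a = 1/2 and b = X/2.
duo_allele_probs <- function(parent, offspring) {
  het <- parent == 1L
  a <- ifelse(het, 0.5, parent / 2)
  b <- ifelse(het, offspring / 2, offspring - parent / 2)
  if (any(b < 0 | b > 1))
    stop("offspring genotype Mendelian-inconsistent with the observed parent",
         call. = FALSE)
  list(a = a, b = b)
}

#' @rdname twin_samplers
#' @export
sample_twin_sibling <- function(siblings, method = c("pool", "pairs")) {
  method <- match.arg(method)
  siblings <- as.matrix(siblings)
  check_geno(siblings, "siblings")
  s <- nrow(siblings)
  if (s < 2)
    stop("sibling mode requires >= 2 genotyped siblings", call. = FALSE)
  if (method == "pool") {
    f <- colSums(siblings) / (2 * s)
    stats::rbinom(ncol(siblings), 2L, f)
  } else {
    pick <- sample.int(s, 2L)
    stats::rbinom(ncol(siblings), 1L, siblings[pick[1], ] / 2) +
      stats::rbinom(ncol(siblings), 1L, siblings[pick[2], ] / 2)
  }
}

## One chunk of R twin replicates for a family_set, as an (R*N) x M integer
## matrix whose first N rows are replicate 1, and so on. RNG draws are
## consumed in replicate order with a single rbinom call per chunk (per-
## replicate loop for the "pairs" sibling rule), so results are identical
## for any chunking of the replicate sequence under the same RNG state.
twin_chunk <- function(fs, R, sibling_method = "pool") {
  n <- nrow(fs$offspring)
  m <- ncol(fs$offspring)
  if (fs$design == "trio") {
    pr <- c(as.vector(fs$parent1) / 2, as.vector(fs$parent2) / 2)
    d <- stats::rbinom(R * length(pr), 1L, rep(pr, times = R))
    d <- matrix(d, ncol = R)                     # 2nm x R
    out <- d[seq_len(n * m), , drop = FALSE] +
      d[n * m + seq_len(n * m), , drop = FALSE]
  } else if (fs$design == "duo") {
    ab <- duo_allele_probs(as.vector(fs$parent1), as.vector(fs$offspring))
    pr <- c(ab$a, ab$b)
    d <- stats::rbinom(R * length(pr), 1L, rep(pr, times = R))
    d <- matrix(d, ncol = R)
    out <- d[seq_len(n * m), , drop = FALSE] +
      d[n * m + seq_len(n * m), , drop = FALSE]
  } else if (sibling_method == "pool") {
    f <- t(vapply(fs$siblings,
                  function(s) colSums(s) / (2 * nrow(s)),
                  numeric(m)))
    if (m == 1) f <- matrix(f, ncol = 1)
    out <- matrix(stats::rbinom(R * n * m, 2L, rep(as.vector(f), times = R)),
                  ncol = R)
  } else {
    out <- vapply(seq_len(R), function(b) {
      t(vapply(fs$siblings, sample_twin_sibling,
               numeric(m), method = "pairs"))
    }, matrix(0, n, m))
    out <- matrix(as.integer(out), ncol = R)
  }
  ## columns are replicates of an n x m matrix in column-major order;
  ## restack as (R*n) x m with replicate-major row blocks
  out <- array(out, dim = c(n, m, R))
  matrix(aperm(out, c(1, 3, 2)), n * R, m)
}

#' Generate a batch of digital-twin replicates for a family set
#'
#' Draws `B` independent digital-twin genotype replicates for every family,
#' conditionally on the observed family genotypes, under the design-specific
#' law of [sample_twin_trio()], [sample_twin_duo()], or
#' [sample_twin_sibling()]. The result is a deterministic function of
#' `(families, B, seed)`: replicates are produced in a fixed order from a
#' single RNG stream, so splitting the batch across chunks (or workers fed
#' consecutive chunks of the stream) cannot change the output.
#'
#' @param families A [family_set()].
#' @param B Number of twin replicates (`>= 1`). 100 is a practical default
#'   for simulation studies with many replicates; 1000 or more is
#'   recommended for a one-off analysis of real data.
#' @param seed Optional integer seed.
#' @param sibling_method Sibling resampling rule, see [twin_samplers].
#' @param chunk_size Replicates generated per internal chunk (memory knob
#'   only; the result is chunk-invariant). Default sizes chunks to roughly
#'   5e6 draws.
#' @return A `B x N x M` integer array of twin genotypes.
#' @export
generate_twin_batch <- function(families, B, seed = NULL,
                                sibling_method = c("pool", "pairs"),
                                chunk_size = NULL) {
  stopifnot(inherits(families, "family_set"), B >= 1)
  sibling_method <- match.arg(sibling_method)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(families$offspring)
  m <- ncol(families$offspring)
  if (is.null(chunk_size)) chunk_size <- max(1L, floor(5e6 / (2 * n * m)))
  out <- array(0L, dim = c(B, n, m))
  done <- 0L
  while (done < B) {
    r <- min(chunk_size, B - done)
    chunk <- twin_chunk(families, r, sibling_method)
    for (b in seq_len(r))
      out[done + b, , ] <- chunk[(b - 1L) * n + seq_len(n), , drop = FALSE]
    done <- done + r
  }
  out
}
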