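## File formats
##
## Native interchange is plain TSV: genotype matrices (row per individual,
## first column `individual_id`, remaining columns one per SNP, additive
## 0/1/2 coding), a FAM-style pedigree table, a phenotype table, and the
## summary-statistic table. VCF is supported for genotype interchange
## (unphased biallelic records; GT collapsed to dosage).

#' Write / read an additive-coded genotype matrix as TSV
#'
#' @param genotypes `n x m` matrix with entries 0/1/2 (NA allowed for
#'   missing); column names are the SNP ids.
#' @param individual_ids Row identifiers (default `ind1..indN`).
#' @param path Output file.
#' @return `write_genotypes()`: `path` invisibly. `read_genotypes()`: a list
#'   with `genotypes` (integer matrix, SNP ids as column names, NA for
#'   missing), `snp_ids`, `individual_ids`.
#' @export
write_genotypes <- function(genotypes, path, individual_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(individual_ids))
    individual_ids <- rownames(genotypes)
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(genotypes)))
  snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  df <- data.frame(individual_id = individual_ids, genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("individual_id", snp_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @param format `"tsv_additive"` (native) or `"vcf"` (requires the vcfR
#'   package; biallelic records only, GT collapsed to dosage, `./.` read as
#'   missing).
#' @export
read_genotypes <- function(path, format = c("tsv_additive", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "vcf") return(read_genotypes_vcf(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "individual_id")
    stop("genotype TSV must start with an `individual_id` column",
         call. = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(g) || any(g[!is.na(g)] != round(g[!is.na(g)])))
    stop("non-integer genotype dosage in ", path, call. = FALSE)
  storage.mode(g) <- "integer"
  if (any(!(g[!is.na(g)] %in% 0:2)))
    stop("genotype dosages outside {0,1,2} in ", path, call. = FALSE)
  rownames(g) <- df$individual_id
  list(genotypes = g, snp_ids = colnames(g), individual_ids = df$individual_id)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the `vcfR` package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic VCF record(s) skipped", call. = FALSE)
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- function(x) {
    x[x %in% c("./.", ".|.", ".")] <- NA
    alleles <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(alleles, function(a) {
      if (anyNA(a) || length(a) == 0) return(NA_integer_)
      av <- suppressWarnings(as.integer(a))
      if (anyNA(av)) return(NA_integer_)
      sum(av != 0L)
    }, 0L)
  }
  g <- t(matrix(dosage(as.vector(gt)), nrow(gt), ncol(gt)))
  rownames(g) <- colnames(gt)
  colnames(g) <- rownames(gt)
  storage.mode(g) <- "integer"
  list(genotypes = g, snp_ids = colnames(g), individual_ids = rownames(g))
}

#' Write an additive genotype matrix as a minimal unphased VCF
#'
#' One biallelic record per SNP (REF `A`, ALT `G`, placeholder positions),
#' dosages rendered as unphased GT (`0/0`, `0/1`, `1/1`, `./.` for missing).
#'
#' @inheritParams write_genotypes
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path, individual_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(individual_ids))
    individual_ids <- rownames(genotypes)
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(genotypes)))
  snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=mrtwin",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", individual_ids), collapse = "\t"))
  records <- vapply(seq_len(ncol(genotypes)), function(j) {
    gt <- gt_code[as.character(genotypes[, j])]
    gt[is.na(gt)] <- "./."
    paste(c("1", j, snp_ids[j], "A", "G", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, "")
  writeLines(c(header, records), path)
  invisible(path)
}

#' Write / read a FAM-style pedigree table
#'
#' Columns: `family_id`, `individual_id`, `father_id`, `mother_id`, `role`
#' (one of offspring/father/mother/sibling); missing parents recorded as
#' `"0"`.
#'
#' @param pedigree Data frame with the columns above.
#' @param path File path.
#' @return The pedigree data frame (reader) or `path` invisibly (writer).
#' @export
write_pedigree <- function(pedigree, path) {
  required <- c("family_id", "individual_id", "father_id", "mother_id", "role")
  stopifnot(all(required %in% names(pedigree)))
  utils::write.table(pedigree[required], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  required <- c("family_id", "individual_id", "father_id", "mother_id", "role")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("pedigree lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$individual_id))
    stop("duplicate individual_id in pedigree", call. = FALSE)
  ok_roles <- c("offspring", "father", "mother", "sibling")
  if (!all(df$role %in% ok_roles))
    stop("pedigree roles must be one of: ", paste(ok_roles, collapse = ", "),
         call. = FALSE)
  df
}

#' Write / read a phenotype table (individual_id, exposure, outcome)
#' @param phenotypes Data frame with `individual_id`, `exposure`, `outcome`.
#' @param path File path.
#' @return The data frame (reader) or `path` invisibly (writer).
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot(all(c("individual_id", "outcome") %in% names(phenotypes)))
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(df))
    stop("phenotype table lacks `individual_id`", call. = FALSE)
  df
}

summary_stat_aliases <- list(
  snp_id = c("snp_id", "SNP", "snp", "rsid", "variant_id"),
  beta_exposure = c("beta_exposure", "beta.exposure", "beta_XE"),
  se_exposure = c("se_exposure", "se.exposure", "se_XE"),
  p_exposure = c("p_exposure", "pval.exposure", "pval_exposure", "p_XE"),
  beta_outcome = c("beta_outcome", "beta.outcome", "beta_XO"),
  se_outcome = c("se_outcome", "se.outcome", "se_XO"),
  p_outcome = c("p_outcome", "pval.outcome", "pval_outcome", "p_XO"),
  n = c("n", "N", "samplesize.exposure"))

#' Read external GWAS summary statistics from TSV
#'
#' Requires columns `snp_id`, `beta_exposure`, `se_exposure`, `p_exposure`,
#' `beta_outcome`, `se_outcome` (directly or via the common aliases used by
#' MR tooling, e.g. `SNP`, `beta.exposure`, `pval.exposure`). Extra columns
#' are carried through untouched; standard errors must be positive.
#'
#' @param path TSV file path.
#' @return An `mr_summary_stats` data frame.
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (canonical in names(summary_stat_aliases)) {
    hit <- intersect(summary_stat_aliases[[canonical]], names(df))
    if (length(hit) > 0 && hit[1] != canonical)
      names(df)[names(df) == hit[1]] <- canonical
  }
  validate_summary_stats(df)
  class(df) <- c("mr_summary_stats", "data.frame")
  df
}

#' @rdname read_summary_stats
#' @param stats An `mr_summary_stats` data frame to write.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble a family set from pedigree, genotype, and phenotype files
#'
#' Infers the design from the pedigree roles: families with father and
#' mother are trios; families with exactly one parent are duos; families of
#' two or more siblings (no parents) use the sibling design, with the first
#' listed sibling as the analyzed proband. All families in one file must
#' share a single design.
#'
#' @param pedigree_path,genotype_path,phenotype_path TSV paths (see
#'   [write_pedigree()], [write_genotypes()], [write_phenotypes()]).
#' @param ... Passed to [family_set()] (e.g. `allow_mendel_errors`).
#' @return A [family_set()] with outcome (and exposure, if present) values.
#' @export
read_family_set <- function(pedigree_path, genotype_path, phenotype_path,
                            ...) {
  ped <- read_pedigree(pedigree_path)
  geno <- read_genotypes(genotype_path)
  phen <- read_phenotypes(phenotype_path)

  missing_ids <- setdiff(ped$individual_id, geno$individual_ids)
  if (length(missing_ids) > 0)
    stop("pedigree/genotype id mismatch: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  g_of <- function(ids) geno$genotypes[match(ids, geno$individual_ids), ,
                                       drop = FALSE]
  fams <- split(ped, factor(ped$family_id, levels = unique(ped$family_id)))
  designs <- vapply(fams, function(f) {
    has_f <- "father" %in% f$role
    has_m <- "mother" %in% f$role
    if (has_f && has_m) "trio"
    else if (has_f || has_m) "duo"
    else "sibling"
  }, "")
  design <- unique(designs)
  if (length(design) != 1)
    stop("mixed family designs in one pedigree: ",
         paste(design, collapse = ", "), call. = FALSE)

  proband_ids <- vapply(fams, function(f) {
    off <- f$individual_id[f$role == "offspring"]
    if (length(off) == 0) off <- f$individual_id[f$role == "sibling"]
    off[1]
  }, "")
  out_idx <- match(proband_ids, phen$individual_id)
  if (anyNA(out_idx))
    stop("phenotype table lacks value(s) for analyzed offspring",
         call. = FALSE)

  args <- list(design = design, outcome = phen$outcome[out_idx],
               snp_ids = geno$snp_ids, family_ids = names(fams))
  if (!is.null(phen$exposure)) args$exposure <- phen$exposure[out_idx]
  if (design == "trio") {
    args$offspring <- g_of(proband_ids)
    args$parent1 <- g_of(vapply(fams, function(f)
      f$individual_id[f$role == "father"][1], ""))
    args$parent2 <- g_of(vapply(fams, function(f)
      f$individual_id[f$role == "mother"][1], ""))
  } else if (design == "duo") {
    args$offspring <- g_of(proband_ids)
    args$parent1 <- g_of(vapply(fams, function(f)
      f$individual_id[f$role %in% c("father", "mother")][1], ""))
  } else {
    args$siblings <- lapply(fams, function(f)
      g_of(f$individual_id[f$role %in% c("sibling", "offspring")]))
    args$offspring <- NULL
  }
  do.call(family_set, c(args, list(...)))
}

#' Write a simulated dataset to a directory of TSV files
#'
#' Emits the native file set: external genotypes and phenotypes, family
#' genotypes (offspring plus parents), a FAM-style pedigree, offspring
#' phenotypes, summary statistics computed from the external cohort, and a
#' JSON sidecar recording the configuration.
#'
#' @param dat A `"sim_dataset"` from [simulate_mr_data()].
#' @param dir Output directory (created if needed).
#' @return Named list of the file paths written, invisibly.
#' @export
write_sim_dataset <- function(dat, dir) {
  stopifnot(inherits(dat, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- dat$families
  n <- nrow(fam$offspring)
  off_id <- paste0("fam", seq_len(n), "_o")
  fat_id <- paste0("fam", seq_len(n), "_f")
  mot_id <- paste0("fam", seq_len(n), "_m")

  paths <- list(
    external_genotypes = file.path(dir, "external_genotypes.tsv"),
    external_phenotypes = file.path(dir, "external_phenotypes.tsv"),
    family_genotypes = file.path(dir, "family_genotypes.tsv"),
    pedigree = file.path(dir, "pedigree.tsv"),
    family_phenotypes = file.path(dir, "family_phenotypes.tsv"),
    summary_stats = file.path(dir, "summary_stats.tsv"),
    config = file.path(dir, "config.json"))

  ext <- dat$external$genotypes
  write_genotypes(ext, paths$external_genotypes,
                  individual_ids = paste0("ext", seq_len(nrow(ext))))
  utils::write.table(
    data.frame(individual_id = paste0("ext", seq_len(nrow(ext))),
               exposure = dat$external$exposure,
               outcome = dat$external$outcome),
    paths$external_phenotypes, sep = "\t", quote = FALSE, row.names = FALSE)

  fam_g <- rbind(fam$offspring, fam$parent1, fam$parent2)
  colnames(fam_g) <- dat$snp_ids
  write_genotypes(fam_g, paths$family_genotypes,
                  individual_ids = c(off_id, fat_id, mot_id))
  write_pedigree(data.frame(
    family_id = rep(paste0("fam", seq_len(n)), 3),
    individual_id = c(off_id, fat_id, mot_id),
    father_id = c(fat_id, rep("0", 2 * n)),
    mother_id = c(mot_id, rep("0", 2 * n)),
    role = rep(c("offspring", "father", "mother"), each = n)),
    paths$pedigree)
  write_phenotypes(data.frame(individual_id = off_id,
                              exposure = fam$exposure,
                              outcome = fam$outcome),
                   paths$family_phenotypes)
  ss <- suppressWarnings(
    gwas_summary_stats(ext, dat$external$exposure, dat$external$outcome))
  write_summary_stats(ss, paths$summary_stats)
  cfg <- dat$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(paths)
}

#' Generate the small on-disk fixture dataset
#'
#' Writes a 20-family, 10-SNP trio dataset (5 causal SNPs, fixation index
#' 0.01, exposure heritability 0.2) with a chosen causal effect, plus
#' summary statistics computed from a matching 2,000-sample external cohort.
#' Fixed seed implies byte-identical output files.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param beta_causal_EO Causal effect in the generating model (0 = null
#'   fixture).
#' @param gamma_confound Confounding strength of the population label.
#' @return Named list of file paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 42, beta_causal_EO = 0,
                          gamma_confound = 0.4) {
  cfg <- sim_config(n_external = 2000, n_families = 20, m_snps = 10,
                    m_causal = 5, fst = 0.01, h2 = 0.2,
                    gamma_confound = gamma_confound,
                    beta_causal_EO = beta_causal_EO, seed = seed)
  write_sim_dataset(simulate_mr_data(cfg), dir)
}
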