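#' Genotype matrix container
#'
#' Samples by biallelic loci, with per-locus chromosome metadata and
#' per-sample sex/immigration status. Calls are alternate-allele dosages:
#' `{0, 1, 2}` on autosomes and on the male Z, `{0, 1}` (single copy) on the
#' female Z, `NA` for missing. Female Z entries are hemizygous: all per-locus
#' statistics (allele frequency, call rate, Hardy-Weinberg, diversity) count
#' allele copies, two for diploid calls and one for female Z calls.
#'
#' @param dosage numeric/integer matrix, samples in rows (rownames = sample
#'   ids), loci in columns.
#' @param loci data frame with `snp_id`, `chrom`, `pos_bp` (one row per
#'   column of `dosage`).
#' @param samples data frame with `id`, `sex` (`"M"`/`"F"`/`NA`) and
#'   optionally `status` (`"local"`/`"immigrant"`) plus free extra columns.
#' @param z_chrom chromosome label(s) treated as the Z.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, loci, samples, z_chrom = "Z") {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(loci) == ncol(dosage), nrow(samples) == nrow(dosage))
  if (is.null(loci$snp_id)) loci$snp_id <- sprintf("snp%05d", seq_len(nrow(loci)))
  loci$chrom <- as.character(loci$chrom)
  loci$is_z <- loci$chrom %in% z_chrom
  samples$id <- as.character(samples$id)
  if (is.null(samples$sex)) samples$sex <- NA_character_
  if (is.null(samples$status)) samples$status <- NA_character_
  rownames(dosage) <- samples$id
  colnames(dosage) <- loci$snp_id
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop_cfg("dosages must lie in [0, 2]")
  bad <- loci$is_z & vapply(seq_len(ncol(dosage)), function(j)
    any(dosage[samples$sex == "F" & !is.na(samples$sex), j] > 1, na.rm = TRUE),
    logical(1))
  if (any(bad))
    stop_cfg("female Z calls must be single-copy (0/1); found dosage 2 at %d loci",
             sum(bad))
  g <- list(dosage = dosage, loci = loci, samples = samples)
  class(g) <- "geno_matrix"
  g
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d loci (%d autosomal, %d Z)\n",
              nrow(x$dosage), ncol(x$dosage), sum(!x$loci$is_z), sum(x$loci$is_z)))
  cat(sprintf("  missing call rate %.3f\n", mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Number of allele copies underlying each call
#'
#' @param g a `geno_matrix`.
#' @return integer matrix of the same shape as `g$dosage`: 1 for female Z
#'   calls, 2 elsewhere (`NA` treated as its nominal copy number).
#' @export
copy_number <- function(g) {
  cn <- matrix(2L, nrow(g$dosage), ncol(g$dosage))
  fem <- which(g$samples$sex == "F")
  if (length(fem) && any(g$loci$is_z)) cn[fem, g$loci$is_z] <- 1L
  cn
}

#' Subset a genotype matrix
#' @param g a `geno_matrix`.
#' @param loci_idx logical/integer index over loci (columns).
#' @param sample_idx logical/integer index over samples (rows).
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(g, loci_idx = NULL, sample_idx = NULL) {
  if (!is.null(sample_idx)) {
    g$dosage <- g$dosage[sample_idx, , drop = FALSE]
    g$samples <- g$samples[sample_idx, , drop = FALSE]
  }
  if (!is.null(loci_idx)) {
    g$dosage <- g$dosage[, loci_idx, drop = FALSE]
    g$loci <- g$loci[loci_idx, , drop = FALSE]
  }
  rownames(g$samples) <- NULL; rownames(g$loci) <- NULL
  g
}

#' Copy-aware alternate-allele frequency per locus
#' @param g a `geno_matrix`.
#' @return numeric vector of frequencies (NaN where no calls).
#' @export
allele_freq <- function(g) {
  cn <- copy_number(g)
  cn[is.na(g$dosage)] <- 0L
  d <- g$dosage; d[is.na(d)] <- 0
  colSums(d) / colSums(cn)
}

#' Minor-allele frequency per locus (copy-aware)
#' @param g a `geno_matrix`.
#' @return numeric vector in `[0, 0.5]`.
#' @export
locus_maf <- function(g) {
  p <- allele_freq(g)
  pmin(p, 1 - p)
}

#' Per-locus call rate
#' @param g a `geno_matrix`.
#' @return fraction of non-missing calls per locus.
#' @export
locus_call_rate <- function(g) colMeans(!is.na(g$dosage))
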