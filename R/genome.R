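# Genome primitives for the forward simulator: locus tables, founder and
# immigrant allele-frequency pools, meiosis with recombination, and simple
# diversity summaries. Alleles are coded 0/1; haplotypes are integer vectors
# over the loci of one chromosome set (all autosomes concatenated, or the Z).

#' Build the marker table for a simulation configuration
#'
#' Autosomal markers are spread evenly over `n_autosomes` chromosomes of
#' length `autosome_length_bp`; Z markers over a single Z chromosome.
#' Positions are uniform random, then sorted within chromosomes.
#'
#' @param config a [sim_config()].
#' @return data frame with `chrom`, `pos_bp`, `is_z`, and the per-chromosome
#'   map length in Morgans as attribute `morgans`.
#' @export
make_locus_table <- function(config) {
  na <- config$n_autosomal_snps
  nz <- config$n_z_snps
  chrom_a <- sort(rep_len(seq_len(config$n_autosomes), na))
  pos_a <- unlist(lapply(split(seq_len(na), chrom_a), function(i)
    sort(stats::runif(length(i), 1, config$autosome_length_bp))))
  loci <- data.frame(
    chrom = c(as.character(chrom_a), rep("Z", nz)),
    pos_bp = c(pos_a, sort(stats::runif(nz, 1, config$z_length_bp))),
    is_z = c(rep(FALSE, na), rep(TRUE, nz)),
    stringsAsFactors = FALSE
  )
  morgans <- c(
    stats::setNames(rep(config$autosome_length_bp * config$recomb_cm_per_mb / 1e8,
                        config$n_autosomes), as.character(seq_len(config$n_autosomes))),
    Z = config$z_length_bp * config$recomb_cm_per_mb / 1e8
  )
  attr(loci, "morgans") <- morgans
  loci
}

#' Draw founder allele frequencies
#'
#' Frequencies come from the configured Beta distribution, redrawn until they
#' lie in `[0.05, 0.95]` (an ascertained-panel convention: chip SNPs are
#' polymorphic and common).
#' @param n number of loci.
#' @param beta two Beta parameters.
#' @return numeric vector of alternate-allele frequencies.
#' @export
draw_founder_freqs <- function(n, beta = c(1, 1)) {
  p <- stats::rbeta(n, beta[1], beta[2])
  bad <- which(p < 0.05 | p > 0.95)
  while (length(bad)) {
    p[bad] <- stats::rbeta(length(bad), beta[1], beta[2])
    bad <- bad[p[bad] < 0.05 | p[bad] > 0.95]
  }
  p
}

#' Immigrant-pool allele frequencies (Balding-Nichols)
#'
#' The external pool that supplies immigrants is differentiated from the
#' founder pool by `fst`: each locus frequency is drawn from
#' `Beta(p (1 - F)/F, (1 - p)(1 - F)/F)`. `fst = 0` returns the founder
#' frequencies unchanged.
#'
#' @param p founder allele frequencies.
#' @param fst Balding-Nichols differentiation parameter, in `[0, 1)`.
#' @return perturbed frequency vector of the same length.
#' @export
balding_nichols_freqs <- function(p, fst) {
  stopifnot(fst >= 0, fst < 1)
  if (fst == 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  stats::rbeta(length(p), a, b)
}

#' Immigrant-pool allele frequencies at a target realized F_ST
#'
#' The simulator's `immigrant_divergence_fst` is the *realized* pairwise
#' F_ST between the immigrant pool and the founder pool. Because only the
#' external branch drifts (the founder frequencies are the reference), a
#' Balding-Nichols draw at parameter `F` yields a pairwise Hudson F_ST of
#' `F/2`; this wrapper therefore draws at twice the target.
#'
#' @param p founder allele frequencies.
#' @param fst target realized founder-immigrant F_ST, in `[0, 0.5)`.
#' @return perturbed frequency vector.
#' @export
immigrant_pool_freqs <- function(p, fst) {
  stopifnot(fst >= 0, fst < 0.5)
  balding_nichols_freqs(p, 2 * fst)
}

#' Independent haplotypes from a frequency pool
#' @param n number of haplotypes.
#' @param p per-locus allele frequencies.
#' @return integer matrix `n x length(p)` of 0/1 alleles.
#' @export
draw_haplotypes <- function(n, p) {
  matrix(stats::rbinom(n * length(p), 1L, rep(p, each = n)), nrow = n)
}

#' One meiotic gamete with recombination
#'
#' Crossover counts per chromosome are Poisson with mean equal to the map
#' length in Morgans; crossover positions are uniform on the physical map
#' (no interference); the starting haplotype is chosen at random.
#'
#' @param h1,h2 the parent's two haplotypes (0/1 integer vectors over loci).
#' @param chrom chromosome label per locus.
#' @param pos_rel per-locus relative position within its chromosome, in
#'   `[0, 1]`.
#' @param morgans named map lengths (Morgans) per chromosome.
#' @return an integer gamete vector.
#' @export
meiosis_gamete <- function(h1, h2, chrom, pos_rel, morgans) {
  out <- integer(length(h1))
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    m <- morgans[[cc]]
    nx <- stats::rpois(1L, m)
    start <- sample.int(2L, 1L) - 1L          # 0 -> h1 first, 1 -> h2 first
    if (nx == 0L) {
      out[idx] <- if (start == 0L) h1[idx] else h2[idx]
    } else {
      brk <- sort(stats::runif(nx))
      seg <- findInterval(pos_rel[idx], brk)
      pick <- (start + seg) %% 2L
      out[idx] <- ifelse(pick == 0L, h1[idx], h2[idx])
    }
  }
  out
}

#' Fraction of Z-chromosome copies carried by males
#'
#' In a ZW system males carry two Z copies and females one, so with an equal
#' sex ratio exactly two-thirds of all Z copies reside in males. This is a
#' census identity, not an estimate.
#'
#' @param sex character vector of `"M"`/`"F"`.
#' @return `2 n_M / (2 n_M + n_F)`.
#' @export
z_copy_fraction <- function(sex) {
  nm <- sum(sex == "M"); nf <- sum(sex == "F")
  2 * nm / (2 * nm + nf)
}

#' Nucleotide diversity of a set of allele copies
#'
#' Unbiased per-locus expected heterozygosity `n/(n-1) * 2 p (1 - p)` where
#' `n` is the number of allele copies at the locus, averaged across loci.
#'
#' @param alt_count alternate-allele copies per locus.
#' @param n_copies total allele copies per locus.
#' @return mean diversity across loci with at least two copies.
#' @export
nucleotide_diversity <- function(alt_count, n_copies) {
  ok <- n_copies >= 2
  p <- alt_count[ok] / n_copies[ok]
  mean(n_copies[ok] / (n_copies[ok] - 1) * 2 * p * (1 - p))
}

#' Z-to-autosome nucleotide diversity of a simulated cohort
#'
#' Diversity ([nucleotide_diversity()]) among the breeders of one simulated
#' year, computed copy-aware on the Z (two copies per male, one per female).
#' With an equal sex ratio the effective population size of the Z is 3/4 of
#' the autosomal one, so in long neutral runs the ratio converges near 3/4.
#'
#' @param sim a `woodsim` run with genotype tracking and an archive covering
#'   the breeders of `year`.
#' @param year breeding season to census (default: last).
#' @return list with `pi_autosome`, `pi_z`, `ratio`.
#' @export
z_autosome_diversity <- function(sim, year = max(sim$breeding$year)) {
  b <- sim$breeding[sim$breeding$year == year, ]
  ids <- unique(c(b$male_id, b$female_id))
  miss <- setdiff(ids, sim$genotyped_ids)
  if (length(miss))
    stop_cfg("%d breeders of year %d are not in the genotype archive",
             length(miss), year)
  d <- sim$dosage[as.character(ids), , drop = FALSE]
  sex <- sim$pedigree$sex[match(ids, sim$pedigree$id)]
  is_z <- sim$loci$is_z
  da <- d[, !is_z, drop = FALSE]
  dz <- d[, is_z, drop = FALSE]
  pi_a <- nucleotide_diversity(colSums(da, na.rm = TRUE),
                               2 * colSums(!is.na(da)))
  cn <- ifelse(sex == "F", 1L, 2L)
  pi_z <- nucleotide_diversity(colSums(dz, na.rm = TRUE),
                               colSums((!is.na(dz)) * cn))
  list(pi_autosome = pi_a, pi_z = pi_z, ratio = pi_z / pi_a)
}
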