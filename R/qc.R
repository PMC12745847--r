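#' Quality-control thresholds
#'
#' Defaults follow common SNP-chip practice for wild-population panels:
#' loci are kept when genotyping call rate exceeds 95%, minor allele
#' frequency exceeds 0.05, and the Hardy-Weinberg exact test p-value exceeds
#' 0.001.
#'
#' @param min_call_rate per-locus call-rate threshold (keep if strictly above).
#' @param min_maf minor-allele-frequency threshold (keep if strictly above).
#' @param hwe_alpha Hardy-Weinberg exact-test threshold (keep if p strictly
#'   above).
#' @param max_sample_missing optional per-sample missingness filter (drop
#'   samples with a higher missing fraction); `NULL` disables it.
#' @param hwe_founders_only restrict the HWE test to samples flagged
#'   `status == "local"` with founder-style usage; default uses all samples.
#' @return an object of class `qc_params`.
#' @export
qc_params <- function(min_call_rate = 0.95, min_maf = 0.05, hwe_alpha = 0.001,
                      max_sample_missing = NULL, hwe_founders_only = FALSE) {
  for (v in c(min_call_rate, min_maf, hwe_alpha))
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop_cfg("QC thresholds must lie strictly inside (0, 1)")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, max_sample_missing = max_sample_missing,
                 hwe_founders_only = hwe_founders_only),
            class = "qc_params")
}

#' Hardy-Weinberg exact test
#'
#' Two-sided conditional exact test: conditional on the observed allele
#' counts, the p-value sums the probabilities of all heterozygote counts that
#' are no more likely than the observed one (no mid-p adjustment, mirroring
#' PLINK's default).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return the exact p-value in `[0, 1]`.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_cfg("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop_cfg("Hardy-Weinberg test needs at least one genotype")
  nA <- 2 * n_AA + n_Aa
  # possible heterozygote counts share the parity of nA
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Apply locus-level quality control
#'
#' Removes loci failing any of the call-rate, minor-allele-frequency, or
#' Hardy-Weinberg filters in [qc_params()]. MAF and call rate count allele
#' copies (two per diploid call, one per female Z call). The HWE test uses
#' all diploid calls on autosomes and male-only genotypes on the Z; the three
#' filters are evaluated on the input matrix, so the result is independent of
#' filter order.
#'
#' @param g a [geno_matrix()].
#' @param params a [qc_params()].
#' @return list with the filtered `geno_matrix` (`$genotypes`) and a
#'   `qc_report` (`$report`) of per-filter failure counts.
#' @export
apply_qc <- function(g, params = qc_params()) {
  stopifnot(inherits(g, "geno_matrix"))
  if (nrow(g$dosage) < 2) stop_cfg("QC needs at least 2 samples")
  n_samples_in <- nrow(g$dosage)
  dropped_samples <- 0L
  if (!is.null(params$max_sample_missing)) {
    miss <- rowMeans(is.na(g$dosage))
    keep_s <- miss <= params$max_sample_missing
    dropped_samples <- sum(!keep_s)
    g <- subset_geno(g, sample_idx = keep_s)
  }
  L <- ncol(g$dosage)
  cr <- locus_call_rate(g)
  maf <- locus_maf(g)
  hwe_g <- g
  if (isTRUE(params$hwe_founders_only) && !all(is.na(g$samples$status)))
    hwe_g <- subset_geno(g, sample_idx = g$samples$status %in% "local")
  hwe_p <- locus_hwe_p(hwe_g)
  fail_cr <- cr <= params$min_call_rate
  fail_maf <- maf <= params$min_maf
  fail_hwe <- !is.na(hwe_p) & hwe_p <= params$hwe_alpha
  keep <- !(fail_cr | fail_maf | fail_hwe)
  report <- structure(list(
    n_loci_in = L,
    n_fail_call_rate = sum(fail_cr),
    n_fail_maf = sum(fail_maf),
    n_fail_hwe = sum(fail_hwe),
    n_removed = sum(!keep),
    n_kept = sum(keep),
    n_samples_in = n_samples_in,
    n_samples_removed = dropped_samples,
    all_removed = !any(keep),
    params = params
  ), class = "qc_report")
  out <- subset_geno(g, loci_idx = keep)
  attr(out, "provenance") <- unique(c(attr(g, "provenance"), "maf_filtered"))
  list(genotypes = out, report = report)
}

# Per-locus HWE exact p: autosomes on all diploid calls, Z on males only
# (female Z calls are haploid and carry no HWE information). Loci with no
# usable genotypes get NA.
locus_hwe_p <- function(g) {
  d <- g$dosage
  male <- g$samples$sex == "M" & !is.na(g$samples$sex)
  p <- numeric(ncol(d))
  for (j in seq_len(ncol(d))) {
    x <- if (g$loci$is_z[j]) d[male, j] else d[, j]
    x <- x[!is.na(x)]
    if (!length(x)) { p[j] <- NA_real_; next }
    p[j] <- hwe_exact_p(sum(x == 0), sum(x == 1), sum(x == 2))
  }
  p
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  loci in: %d, removed: %d, kept: %d\n",
              x$n_loci_in, x$n_removed, x$n_kept))
  cat(sprintf("  failures - call rate: %d, MAF: %d, HWE: %d\n",
              x$n_fail_call_rate, x$n_fail_maf, x$n_fail_hwe))
  if (x$n_samples_removed > 0)
    cat(sprintf("  samples removed for missingness: %d of %d\n",
                x$n_samples_removed, x$n_samples_in))
  if (x$all_removed) cat("  NOTE: all loci removed\n")
  invisible(x)
}
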