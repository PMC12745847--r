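#' Linkage-disequilibrium pruning parameters
#'
#' @param r2_max maximum allowed squared genotype correlation between loci in
#'   a window.
#' @param window_bp window width in base pairs.
#' @param step_snps number of loci the window start advances between windows.
#' @return an object of class `ld_prune_params`.
#' @export
ld_prune_params <- function(r2_max = 0.2, window_bp = 50000, step_snps = 50) {
  if (r2_max <= 0 || r2_max > 1) stop_cfg("'r2_max' must be in (0, 1]")
  if (window_bp <= 0 || step_snps < 1) stop_cfg("invalid window/step")
  structure(list(r2_max = r2_max, window_bp = window_bp,
                 step_snps = as.integer(step_snps)),
            class = "ld_prune_params")
}

#' Greedy LD pruning
#'
#' Within sliding windows of `window_bp` advanced by `step_snps` loci (per
#' chromosome, loci ordered by position), any pair of retained loci with
#' squared genotype correlation above `r2_max` loses its later member.
#' Missing calls are mean-imputed for the correlation; monomorphic loci never
#' trigger a drop. Deterministic.
#'
#' @param g a [geno_matrix()].
#' @param params an [ld_prune_params()].
#' @return logical vector over loci: `TRUE` = kept. Use
#'   `subset_geno(g, ld_prune(g, p))` to materialise the pruned matrix.
#' @export
ld_prune <- function(g, params = ld_prune_params()) {
  stopifnot(inherits(g, "geno_matrix"))
  L <- ncol(g$dosage)
  keep <- rep(TRUE, L)
  # chromosomes must form contiguous blocks with nondecreasing positions
  rl <- rle(g$loci$chrom)
  if (anyDuplicated(rl$values) ||
      any(vapply(unique(g$loci$chrom), function(cc)
        is.unsorted(g$loci$pos_bp[g$loci$chrom == cc]), logical(1))))
    stop_cfg("loci must be sorted by (chrom, pos) before LD pruning")
  X <- g$dosage
  # mean-impute per locus for correlation purposes
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  for (cc in unique(g$loci$chrom)) {
    jj <- which(g$loci$chrom == cc)
    pos <- g$loci$pos_bp[jj]
    nl <- length(jj)
    starts <- seq(1L, nl, by = params$step_snps)
    for (s in starts) {
      w <- which(pos >= pos[s] & pos <= pos[s] + params$window_bp)
      w <- w[w >= s]
      w <- w[keep[jj[w]]]
      if (length(w) < 2) next
      cols <- jj[w]
      r2 <- suppressWarnings(stats::cor(X[, cols, drop = FALSE]))^2
      r2[!is.finite(r2)] <- 0
      for (a in seq_len(length(cols) - 1)) {
        if (!keep[cols[a]]) next
        hit <- which(r2[a, ] > params$r2_max)
        hit <- hit[hit > a & keep[cols[hit]]]
        if (length(hit)) keep[cols[hit]] <- FALSE
      }
    }
  }
  keep
}

#' Split a genotype matrix into autosomal and Z-only datasets
#'
#' @param g a [geno_matrix()].
#' @param exclude chromosome labels removed from both outputs (e.g., a
#'   chromosome carrying a large inversion).
#' @param z_chrom chromosome label(s) of the Z.
#' @return list with `autosomal` and `z_only` genotype matrices; the two are
#'   disjoint and, together with the excluded loci, exhaust the input.
#' @export
split_datasets <- function(g, exclude = character(), z_chrom = "Z") {
  stopifnot(inherits(g, "geno_matrix"))
  excl <- g$loci$chrom %in% exclude
  is_z <- g$loci$chrom %in% z_chrom & !excl
  auto <- !is_z & !excl
  if (!any(is_z)) warning("no Z loci present: z_only dataset is empty",
                          call. = FALSE)
  list(autosomal = subset_geno(g, loci_idx = auto),
       z_only = subset_geno(g, loci_idx = is_z),
       n_excluded = sum(excl))
}
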