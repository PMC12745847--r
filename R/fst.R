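# Genome-wide differentiation between two groups: per-SNP Weir-Cockerham
# variance components, ratio-of-sums window and global estimates, a Hudson
# cross-check, and the MDS-extreme subset selection.

#' Per-SNP Weir-Cockerham F_ST components
#'
#' Two-group Weir-Cockerham (1984) moments estimator. For each locus the
#' variance components `a` (among groups), `b` (among individuals within
#' groups) and `c` (within individuals) are returned so windows and the
#' global value can be aggregated as ratios of sums; per-locus estimates
#' `a/(a+b+c)` are kept even when negative. Loci monomorphic in both groups
#' have all components zero and an undefined (`NA`) per-locus estimate.
#'
#' @param g a [geno_matrix()] of diploid dosages.
#' @param groups two-level factor/character, one per sample.
#' @return data frame with `snp_id`, `chrom`, `pos_bp`, `a`, `b`, `c`, `fst`.
#' @export
fst_per_snp <- function(g, groups) {
  stopifnot(inherits(g, "geno_matrix"))
  check_diploid(g, "fst_per_snp")
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop_cfg("need exactly two non-empty groups")
  d1 <- g$dosage[groups == lv[1], , drop = FALSE]
  d2 <- g$dosage[groups == lv[2], , drop = FALSE]
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2; p2 <- colMeans(d2, na.rm = TRUE) / 2
  h1 <- colMeans(d1 == 1, na.rm = TRUE); h2 <- colMeans(d2 == 1, na.rm = TRUE)
  comp <- wc_components(n1, p1, h1, n2, p2, h2)
  den <- comp$a + comp$b + comp$c
  data.frame(snp_id = g$loci$snp_id, chrom = g$loci$chrom,
             pos_bp = g$loci$pos_bp, a = comp$a, b = comp$b, c = comp$c,
             fst = ifelse(den == 0, NA_real_, comp$a / den),
             stringsAsFactors = FALSE)
}

# Weir & Cockerham (1984) two-population components, vectorised over loci.
# n_i: individuals genotyped, p_i: alt allele frequency, h_i: observed
# heterozygote frequency.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  zero <- (p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1)
  a[zero] <- 0; b[zero] <- 0; cc[zero] <- 0
  list(a = a, b = b, c = cc)
}

#' Global ratio-of-sums F_ST
#' @param per_snp output of [fst_per_snp()].
#' @return `sum(a) / sum(a + b + c)` over defined loci.
#' @export
global_fst <- function(per_snp) {
  ok <- (per_snp$a + per_snp$b + per_snp$c) != 0
  sum(per_snp$a[ok]) / sum((per_snp$a + per_snp$b + per_snp$c)[ok])
}

#' Windowed F_ST
#'
#' Non-overlapping tiles of `window_bp` (half-open, 0-based starts) per
#' chromosome, each aggregated as a ratio of sums of the Weir-Cockerham
#' components; `fst_mean` is the mean of defined per-locus estimates. Empty
#' windows are kept with `n_snps = 0` and `NA` values.
#'
#' @param per_snp output of [fst_per_snp()].
#' @param window_bp window width.
#' @param step_bp distance between window starts (default = `window_bp`,
#'   i.e., non-overlapping).
#' @return data frame `chrom`, `start_bp`, `end_bp`, `n_snps`, `fst_mean`,
#'   `fst_weighted`.
#' @export
window_fst <- function(per_snp, window_bp = 50000, step_bp = window_bp) {
  rows <- list()
  for (cc in unique(per_snp$chrom)) {
    s <- per_snp[per_snp$chrom == cc, ]
    top <- max(s$pos_bp)
    starts <- seq(0, top, by = step_bp)
    nw <- length(starts)
    if (step_bp == window_bp) {
      # non-overlapping tiles: direct binning
      w <- pmin(nw, floor(s$pos_bp / window_bp) + 1L)
      agg <- function(v) {
        out <- rep(0, nw)
        sm <- rowsum(v, w)
        out[as.integer(rownames(sm))] <- sm
        out
      }
      n <- agg(rep(1, nrow(s)))
      den <- agg(s$a + s$b + s$c)
      num <- agg(s$a)
      fdef <- !is.na(s$fst)
      nms <- agg(fdef * 1)
      sms <- agg(ifelse(fdef, s$fst, 0))
      rows[[cc]] <- data.frame(
        chrom = cc, start_bp = starts, end_bp = starts + window_bp,
        n_snps = as.integer(n),
        fst_mean = ifelse(nms > 0, sms / nms, NA_real_),
        fst_weighted = ifelse(n > 0 & den != 0, num / den, NA_real_),
        stringsAsFactors = FALSE)
    } else {
      sub <- lapply(starts, function(w0) {
        inw <- s$pos_bp >= w0 & s$pos_bp < w0 + window_bp
        den <- sum((s$a + s$b + s$c)[inw])
        data.frame(
          chrom = cc, start_bp = w0, end_bp = w0 + window_bp,
          n_snps = sum(inw),
          fst_mean = if (any(inw & !is.na(s$fst)))
            mean(s$fst[inw], na.rm = TRUE) else NA_real_,
          fst_weighted = if (sum(inw) && den != 0)
            sum(s$a[inw]) / den else NA_real_,
          stringsAsFactors = FALSE)
      })
      rows[[cc]] <- do.call(rbind, sub)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hudson F_ST (cross-check estimator)
#'
#' Ratio-of-sums Hudson estimator on allele copies:
#' numerator `(p1 - p2)^2 - p1 q1/(n1 - 1) - p2 q2/(n2 - 1)`, denominator
#' `p1 q2 + p2 q1`, with `n_i` allele copies. Copy-aware, so usable on Z
#' data and on raw haplotype pools.
#'
#' @param p1,p2 per-locus allele frequencies of the two groups.
#' @param n1,n2 per-locus allele-copy counts.
#' @return ratio-of-sums F_ST.
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  ok <- n1 > 1 & n2 > 1
  p1 <- p1[ok]; p2 <- p2[ok]; n1 <- n1[ok]; n2 <- n2[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

#' MDS-extreme immigrant and local subsets
#'
#' From a [rf_ensemble()] report, picks the `k` immigrants most extreme on
#' MDS axis 1 and the `k` locals most extreme on MDS axis 2, extremeness
#' measured toward each group's own centroid side of the axis. When a
#' kinship pair table is supplied, the maximum within-subset kinship is
#' reported as the screen against the subsets being families.
#'
#' @param report a `classifier_report` with `mds`, `labels` and
#'   `sample_ids`.
#' @param k subset size per group.
#' @param kinship optional [king_robust()] pair table for the kinship screen.
#' @return list with `top_immigrants`, `top_locals` (sample ids),
#'   `max_phi_immigrants`, `max_phi_locals`.
#' @export
extreme_subsets <- function(report, k = 50, kinship = NULL) {
  lab <- as.character(report$labels)
  ids <- report$sample_ids %||% as.character(report$sample_index)
  mds <- report$mds
  pick <- function(group, axis) {
    in_g <- lab == group
    if (sum(in_g) < k)
      stop_cfg("k = %d exceeds the %d samples in group '%s'", k, sum(in_g), group)
    dir <- sign(mean(mds[in_g, axis]) - mean(mds[, axis]))
    if (dir == 0) dir <- 1
    sc <- dir * mds[, axis]
    ids[in_g][order(sc[in_g], decreasing = TRUE)][seq_len(k)]
  }
  top_imm <- pick("immigrant", 1)
  top_loc <- pick("local", 2)
  max_phi <- function(sub) {
    if (is.null(kinship)) return(NA_real_)
    s <- kinship$id_a %in% sub & kinship$id_b %in% sub
    if (!any(s)) return(NA_real_)
    max(kinship$phi[s], na.rm = TRUE)
  }
  list(top_immigrants = top_imm, top_locals = top_loc,
       max_phi_immigrants = max_phi(top_imm),
       max_phi_locals = max_phi(top_loc))
}
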