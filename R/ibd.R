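# Pairwise relatedness estimators. Both estimators are computed for all
# sample pairs at once from indicator-matrix cross-products, so they scale to
# a few thousand samples.

# Pair ids in the order upper.tri() extracts matrix entries (column-major).
pair_index_frame <- function(ids) {
  n <- length(ids)
  i <- unlist(lapply(2:n, function(k) seq_len(k - 1)))
  j <- rep(2:n, times = seq_len(n - 1))
  data.frame(id_a = ids[i], id_b = ids[j], stringsAsFactors = FALSE)
}

upper_vec <- function(M) M[upper.tri(M)]

check_diploid <- function(g, what) {
  fem <- g$samples$sex == "F" & !is.na(g$samples$sex)
  if (any(g$loci$is_z) && any(fem))
    stop_cfg(paste0(what, " needs diploid calls: female Z genotypes are ",
                    "hemizygous. Subset to autosomes or to males, or use ",
                    "z_relatedness() for copy-aware Z relatedness."))
}

#' Method-of-moments identity-by-descent
#'
#' PLINK-style moments estimator: loci with minor allele frequency below
#' `maf_floor` are excluded (IBD estimates are sensitive to rare variants);
#' for each pair the observed IBS0/IBS1/IBS2 counts are combined with the
#' frequency-based expected IBS-given-IBD proportions to solve for
#' P(IBD = 0, 1, 2), the probabilities are clamped to the simplex and
#' renormalised, and the genome fraction shared is
#' `pi_hat = P(IBD=2) + P(IBD=1)/2`.
#'
#' @param g a [geno_matrix()] of diploid dosages (autosomes, or male-only Z).
#' @param maf_floor exclusion threshold for rare variants.
#' @param min_loci pairs with fewer informative (jointly non-missing) loci
#'   are flagged `low_conf`.
#' @return data frame of unordered pairs with `pi_hat` (clamped to the
#'   simplex, as reported by standard toolchains), `pi_raw` (the unclamped
#'   moments estimate, unbiased around zero for unrelated pairs), the clamped
#'   IBD-state probabilities `z0`, `z1`, `z2`, the informative locus count
#'   `n_loci`, and `low_conf`.
#' @export
mom_ibd <- function(g, maf_floor = 0.1, min_loci = 50) {
  stopifnot(inherits(g, "geno_matrix"))
  check_diploid(g, "mom_ibd")
  g <- subset_geno(g, loci_idx = locus_maf(g) >= maf_floor)
  d <- g$dosage
  L <- ncol(d)
  if (L == 0) stop_cfg("no loci left after the MAF floor")
  p <- allele_freq(g); q <- 1 - p
  I0 <- (d == 0) * 1; I1 <- (d == 1) * 1; I2 <- (d == 2) * 1
  I0[is.na(I0)] <- 0; I1[is.na(I1)] <- 0; I2[is.na(I2)] <- 0
  M <- (!is.na(d)) * 1
  N2 <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)
  N0 <- I0 %*% t(I2); N0 <- N0 + t(N0)
  NV <- tcrossprod(M)
  N1 <- NV - N0 - N2
  # expected per-locus IBS proportions given the IBD state
  S00 <- sum(2 * p^2 * q^2)
  S10 <- sum(4 * p^3 * q + 4 * p * q^3)
  S20 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  S11 <- sum(2 * p * q)
  S21 <- sum(p^2 + q^2)
  f <- NV / L    # scale expectations to each pair's informative locus count
  P0 <- N0 / (S00 * f)
  P1 <- (N1 - P0 * S10 * f) / (S11 * f)
  P2 <- (N2 - P0 * S20 * f - P1 * S21 * f) / NV
  pi_raw <- P2 + P1 / 2          # unclamped: unbiased around 0 for unrelated
  clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
  P0 <- clamp01(P0); P1 <- clamp01(P1); P2 <- clamp01(P2)
  s <- P0 + P1 + P2
  P0 <- P0 / s; P1 <- P1 / s; P2 <- P2 / s
  pihat <- P2 + P1 / 2
  out <- pair_index_frame(g$samples$id)
  out$pi_hat <- upper_vec(pihat)
  out$pi_raw <- upper_vec(pi_raw)
  out$z0 <- upper_vec(P0); out$z1 <- upper_vec(P1); out$z2 <- upper_vec(P2)
  out$n_loci <- upper_vec(NV)
  out$low_conf <- out$n_loci < min_loci
  out
}

#' KING-robust pairwise kinship
#'
#' `phi = (N_AaAa - 2 N_AA,aa) / (N_Aa(a) + N_Aa(b))` over loci non-missing
#' in both samples, where `N_AaAa` counts jointly heterozygous loci,
#' `N_AA,aa` opposite homozygotes, and `N_Aa(i)` heterozygous loci of sample
#' i. Robust to population structure; negative values indicate samples from
#' diverged pools.
#'
#' @param g a [geno_matrix()] of diploid dosages.
#' @param classify add a `degree` column via [classify_degree()].
#' @return data frame of unordered pairs with `phi` (NA when the denominator
#'   is zero, flagged `undefined`) and optionally `degree`.
#' @export
king_robust <- function(g, classify = TRUE) {
  stopifnot(inherits(g, "geno_matrix"))
  check_diploid(g, "king_robust")
  d <- g$dosage
  H <- (d == 1) * 1; H[is.na(H)] <- 0
  I0 <- (d == 0) * 1; I0[is.na(I0)] <- 0
  I2 <- (d == 2) * 1; I2[is.na(I2)] <- 0
  M <- (!is.na(d)) * 1
  Nhh <- tcrossprod(H)
  Nopp <- I0 %*% t(I2); Nopp <- Nopp + t(Nopp)
  Ha <- H %*% t(M)           # het in row sample, non-missing in column sample
  den <- Ha + t(Ha)
  phi <- (Nhh - 2 * Nopp) / den
  phi[den == 0] <- NA_real_
  out <- pair_index_frame(g$samples$id)
  out$phi <- upper_vec(phi)
  out$n_hethet <- upper_vec(Nhh)
  out$n_opp <- upper_vec(Nopp)
  out$undefined <- upper_vec(den) == 0
  if (classify) out$degree <- classify_degree(out$phi)
  out
}

#' Kinship degree classes from KING-robust kinship
#'
#' KING's powers-of-one-half cutoffs: duplicate/monozygotic above
#' `1/2^(3/2) = 0.354`; first degree `(0.177, 0.354]`; second
#' `(0.0884, 0.177]`; third `(0.0442, 0.0884]`; unrelated otherwise.
#'
#' @param phi numeric kinship values.
#' @return factor with levels `duplicate`, `first`, `second`, `third`,
#'   `unrelated` (NA propagates).
#' @export
classify_degree <- function(phi) {
  cuts <- 1 / 2^c(3 / 2, 5 / 2, 7 / 2, 9 / 2)  # 0.354, 0.177, 0.0884, 0.0442
  lab <- rep(NA_character_, length(phi))
  lab[phi > cuts[1]] <- "duplicate"
  lab[phi <= cuts[1] & phi > cuts[2]] <- "first"
  lab[phi <= cuts[2] & phi > cuts[3]] <- "second"
  lab[phi <= cuts[3] & phi > cuts[4]] <- "third"
  lab[phi <= cuts[4]] <- "unrelated"
  factor(lab, levels = c("duplicate", "first", "second", "third", "unrelated"))
}

#' Copy-aware relatedness on the Z chromosome
#'
#' Moment estimator on allele copies that accommodates hemizygous female Z
#' calls: with copy numbers `c_a`, `c_b` (1 for female Z, 2 for male Z) the
#' per-pair statistic `2 sum((g_a - c_a p)(g_b - c_b p)) / (c_a c_b sum(p q))`
#' over shared loci has expectation `2 phi` (the relatedness scale of
#' `pi_hat` under additive sharing), so male-male values are directly
#' comparable with diploid estimates.
#'
#' @param g a [geno_matrix()] restricted to Z loci.
#' @return data frame of unordered pairs with raw relatedness `r` and
#'   `pi_hat = min(1, max(0, r))`.
#' @export
z_relatedness <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  if (!all(g$loci$is_z)) stop_cfg("z_relatedness expects Z loci only")
  d <- g$dosage
  cn <- ifelse(g$samples$sex == "F" & !is.na(g$samples$sex), 1, 2)
  p <- allele_freq(g); q <- 1 - p
  Xc <- d - outer(cn, p)
  Xc[is.na(d)] <- 0
  M <- (!is.na(d)) * 1
  num <- tcrossprod(Xc)
  Spq <- (M * matrix(p * q, nrow(M), ncol(M), byrow = TRUE)) %*% t(M)
  r <- 2 * num / (outer(cn, cn) * Spq)
  out <- pair_index_frame(g$samples$id)
  out$r <- upper_vec(r)
  out$pi_hat <- pmin(1, pmax(0, out$r))
  out$n_loci <- upper_vec(tcrossprod(M))
  out
}
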