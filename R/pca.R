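#' Principal component analysis of genotypes
#'
#' Standard genotype PCA: dosages are centred by `2 p` and scaled by
#' `sqrt(2 p (1 - p))` with `p` the sample allele frequency; missing calls
#' are mean-imputed (zero after centring); the scores are the left singular
#' vectors scaled by the singular values. Monomorphic loci are dropped with
#' a warning. Intended for QC'd, LD-pruned autosomal data.
#'
#' @param g a [geno_matrix()].
#' @param n_pc number of components to return scores for.
#' @return object of class `geno_pca`: `scores` (samples x `n_pc`, rownames
#'   are sample ids), `varexp` (fraction of total variance per component,
#'   non-increasing, summing to at most 1), and the `samples` metadata.
#' @export
geno_pca <- function(g, n_pc = 10) {
  stopifnot(inherits(g, "geno_matrix"))
  p <- allele_freq(g)
  mono <- !is.finite(p) | p <= 0 | p >= 1
  if (any(mono)) {
    warning(sprintf("dropping %d monomorphic loci before PCA", sum(mono)),
            call. = FALSE)
    g <- subset_geno(g, loci_idx = !mono)
    p <- p[!mono]
  }
  d <- g$dosage
  X <- sweep(d, 2, 2 * p, "-")
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  n_pc <- min(n_pc, nrow(X) - 1, ncol(X))
  sv <- svd(X)
  varexp <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)
  rownames(scores) <- g$samples$id
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  structure(list(scores = scores, varexp = varexp, samples = g$samples),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("Genotype PCA: %d samples, %d score components\n",
              nrow(x$scores), ncol(x$scores)))
  ve <- utils::head(x$varexp, 5)
  cat("  variance explained:",
      paste(sprintf("PC%d %.2f%%", seq_along(ve), 100 * ve), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.geno_pca <- function(x, dims = c(1, 2), col_by = "status", ...) {
  grp <- x$samples[[col_by]] %||% rep("sample", nrow(x$scores))
  grp <- factor(grp)
  plot(x$scores[, dims[1]], x$scores[, dims[2]], col = as.integer(grp),
       pch = 20, xlab = sprintf("PC%d (%.2f%%)", dims[1], 100 * x$varexp[dims[1]]),
       ylab = sprintf("PC%d (%.2f%%)", dims[2], 100 * x$varexp[dims[2]]), ...)
  graphics::legend("topright", legend = levels(grp), col = seq_along(levels(grp)),
                   pch = 20, bty = "n")
  invisible(x)
}
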