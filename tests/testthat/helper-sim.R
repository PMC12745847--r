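# Shared fixtures, all generated in code.

make_geno <- function(dosage, chrom = "1", pos = NULL, sex = "M",
                      status = NULL, ids = NULL) {
  dosage <- as.matrix(dosage)
  L <- ncol(dosage); n <- nrow(dosage)
  loci <- data.frame(chrom = rep_len(chrom, L),
                     pos_bp = pos %||% (seq_len(L) * 1000))
  samples <- data.frame(id = ids %||% paste0("s", seq_len(n)),
                        sex = rep_len(sex, n))
  if (!is.null(status)) samples$status <- rep_len(status, n)
  geno_matrix(dosage, loci, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw n diploid samples from allele frequencies p
draw_pool <- function(n, p) {
  matrix(stats::rbinom(n * length(p), 2, rep(p, each = n)), nrow = n)
}

# one small tracked simulation shared across test files (built once)
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- run_simulation(sim_preset(
      "desk", n_boxes = 150L, occupancy = 0.4, n_autosomal_snps = 600L,
      n_z_snps = 150L, n_years = 10L, max_genotyped = Inf, seed = 99L))
  }
  .sim_cache$sim
}

# full-sib-mating construction on a chip-density test genome; returns a
# geno_matrix of inbred offspring (expected inbreeding F = 1/4) plus the
# genome span in kb
inbred_offspring <- function(n_off = 20, L = 10000, n_chrom = 5,
                             chrom_len = 5e7, morgans = 0.5, seed = 5) {
  set.seed(seed)
  chrom <- sort(rep_len(seq_len(n_chrom), L))
  pos <- unlist(lapply(split(seq_len(L), chrom), function(i)
    sort(stats::runif(length(i), 1, chrom_len))))
  p <- stats::runif(L, 0.1, 0.9)
  cl <- as.character(chrom)
  mg <- stats::setNames(rep(morgans, n_chrom), as.character(seq_len(n_chrom)))
  gam <- function(h1, h2) meiosis_gamete(h1, h2, cl, pos / chrom_len, mg)
  off <- vector("list", n_off)
  for (k in seq_len(n_off)) {
    gp <- replicate(4, stats::rbinom(L, 1, p))
    s1 <- list(gam(gp[, 1], gp[, 2]), gam(gp[, 3], gp[, 4]))
    s2 <- list(gam(gp[, 1], gp[, 2]), gam(gp[, 3], gp[, 4]))
    off[[k]] <- gam(s1[[1]], s1[[2]]) + gam(s2[[1]], s2[[2]])
  }
  g <- geno_matrix(do.call(rbind, off),
                   data.frame(chrom = cl, pos_bp = pos),
                   data.frame(id = paste0("o", seq_len(n_off)), sex = "M"))
  list(genotypes = g,
       genome_kb = sum(tapply(pos, chrom, function(x) diff(range(x)))) / 1000)
}

# random QC-style genotype table counts
rand_geno_counts <- function(max_n = 30) {
  n <- sample(2:max_n, 1)
  nAA <- sample(0:n, 1)
  nAa <- if (n - nAA > 0) sample(0:(n - nAA), 1) else 0
  c(nAA, nAa, n - nAA - nAa)
}
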