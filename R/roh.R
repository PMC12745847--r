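#' Runs-of-homozygosity scanning parameters
#'
#' PLINK-style defaults: a 50-SNP window slides one SNP at a time; a window
#' is homozygous-compatible when it contains at most 1 heterozygous and at
#' most 5 missing calls; a SNP is in candidate state when at least 5% of the
#' windows spanning it are compatible; candidate runs are emitted when they
#' hold at least 100 SNPs, span at least 1000 kb, average no more than one
#' SNP per 50 kb, and contain no inter-SNP gap above 1000 kb.
#'
#' @param window_snps scanning window size in SNPs.
#' @param window_het maximum heterozygous calls per compatible window.
#' @param window_missing maximum missing calls per compatible window.
#' @param hit_threshold minimum fraction of spanning windows that must be
#'   compatible for a SNP to enter candidate state.
#' @param min_snps minimum SNPs per emitted segment.
#' @param min_length_kb minimum segment span.
#' @param max_density_kb_per_snp maximum kb per SNP inside a segment.
#' @param max_gap_kb maximum gap between consecutive segment SNPs.
#' @return an object of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50, window_het = 1, window_missing = 5,
                       hit_threshold = 0.05, min_snps = 100,
                       min_length_kb = 1000, max_density_kb_per_snp = 50,
                       max_gap_kb = 1000) {
  structure(list(window_snps = as.integer(window_snps),
                 window_het = as.integer(window_het),
                 window_missing = as.integer(window_missing),
                 hit_threshold = hit_threshold,
                 min_snps = as.integer(min_snps),
                 min_length_kb = min_length_kb,
                 max_density_kb_per_snp = max_density_kb_per_snp,
                 max_gap_kb = max_gap_kb),
            class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' Scanning-window ROH caller on autosomal diploid genotypes. The input
#' should carry no MAF filter and no LD pruning (rare variants and LD
#' structure are informative for homozygous runs); matrices marked as
#' MAF-filtered or pruned by [apply_qc()]/[apply_ld_prune()] are refused
#' unless `allow_filtered = TRUE`.
#'
#' @param g a [geno_matrix()]; Z loci are ignored with a message.
#' @param params a [roh_params()].
#' @param allow_filtered permit input marked MAF-filtered or LD-pruned.
#' @return data frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_kb`, with per-sample summaries via
#'   [roh_summary()].
#' @export
detect_roh <- function(g, params = roh_params(), allow_filtered = FALSE) {
  stopifnot(inherits(g, "geno_matrix"))
  prov <- attr(g, "provenance") %||% character(0)
  if (!allow_filtered && any(c("maf_filtered", "ld_pruned") %in% prov))
    stop_cfg(paste0("input was MAF-filtered or LD-pruned; ROH should be ",
                    "called on unfiltered autosomal data ",
                    "(override with allow_filtered = TRUE)"))
  if (any(g$loci$is_z)) {
    message("ignoring ", sum(g$loci$is_z), " Z loci for ROH detection")
    g <- subset_geno(g, loci_idx = !g$loci$is_z)
  }
  segs <- list()
  for (s in seq_len(nrow(g$dosage))) {
    for (cc in unique(g$loci$chrom)) {
      jj <- which(g$loci$chrom == cc)
      res <- roh_scan_one(g$dosage[s, jj], g$loci$pos_bp[jj], params)
      if (!is.null(res) && nrow(res)) {
        res$sample_id <- g$samples$id[s]
        res$chrom <- cc
        segs[[length(segs) + 1L]] <- res
      }
    }
  }
  if (!length(segs))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), length_kb = numeric(0)))
  out <- do.call(rbind, segs)
  out[, c("sample_id", "chrom", "start_bp", "end_bp", "n_snps", "length_kb")]
}

# Window scan of one sample x one chromosome. Returns candidate runs passing
# the segment-level constraints.
roh_scan_one <- function(x, pos, params) {
  L <- length(x)
  W <- params$window_snps
  if (L < W) return(NULL)
  het <- as.integer(!is.na(x) & x == 1)
  mis <- as.integer(is.na(x))
  ch <- c(0L, cumsum(het)); cm <- c(0L, cumsum(mis))
  nW <- L - W + 1L
  wi <- seq_len(nW)
  ok <- (ch[wi + W] - ch[wi]) <= params$window_het &
    (cm[wi + W] - cm[wi]) <= params$window_missing
  cok <- c(0L, cumsum(as.integer(ok)))
  s <- seq_len(L)
  lo <- pmax(1L, s - W + 1L)
  hi <- pmin(s, nW)
  n_span <- pmax(0L, hi - lo + 1L)
  n_ok <- ifelse(n_span > 0, cok[hi + 1L] - cok[lo], 0L)
  cand <- n_span > 0 & n_ok / pmax(1L, n_span) >= params$hit_threshold
  runs_from_candidates(cand, pos, params)
}

runs_from_candidates <- function(cand, pos, params) {
  if (!any(cand)) return(NULL)
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i <- starts[k]:ends[k]
    # split on physical gaps
    gaps <- which(diff(pos[i]) > params$max_gap_kb * 1000)
    pieces <- split(i, cumsum(seq_along(i) %in% (gaps + 1L)))
    for (pc in pieces) {
      n <- length(pc)
      len_kb <- (pos[pc[n]] - pos[pc[1]]) / 1000
      if (n >= params$min_snps && len_kb >= params$min_length_kb &&
          len_kb / n <= params$max_density_kb_per_snp)
        out[[length(out) + 1L]] <- data.frame(
          start_bp = pos[pc[1]], end_bp = pos[pc[n]],
          n_snps = n, length_kb = len_kb)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Per-sample ROH summaries
#'
#' @param segments output of [detect_roh()].
#' @param sample_ids ids to summarise (zero-segment samples get zero rows
#'   otherwise).
#' @param genome_kb total autosomal span in kb; when given, the genome
#'   fraction in ROH (`f_roh`) is added.
#' @return data frame with `sample_id`, `n_roh`, `mean_length_kb`,
#'   `total_kb`, and optionally `f_roh`.
#' @export
roh_summary <- function(segments, sample_ids = unique(segments$sample_id),
                        genome_kb = NULL) {
  out <- data.frame(sample_id = as.character(sample_ids),
                    stringsAsFactors = FALSE)
  sp <- split(segments$length_kb, segments$sample_id)
  out$n_roh <- vapply(out$sample_id, function(i)
    length(sp[[i]] %||% numeric(0)), integer(1))
  out$mean_length_kb <- vapply(out$sample_id, function(i) {
    v <- sp[[i]] %||% numeric(0)
    if (length(v)) mean(v) else 0
  }, numeric(1))
  out$total_kb <- vapply(out$sample_id, function(i)
    sum(sp[[i]] %||% numeric(0)), numeric(1))
  if (!is.null(genome_kb)) out$f_roh <- out$total_kb / genome_kb
  rownames(out) <- NULL
  out
}

#' LD-prune a genotype matrix and mark its provenance
#'
#' Convenience wrapper around [ld_prune()] that subsets the matrix and tags
#' it `ld_pruned` so downstream analyses that require unpruned input (ROH)
#' can refuse it.
#'
#' @param g a [geno_matrix()].
#' @param params an [ld_prune_params()].
#' @return the pruned `geno_matrix`.
#' @export
apply_ld_prune <- function(g, params = ld_prune_params()) {
  keep <- ld_prune(g, params)
  out <- subset_geno(g, loci_idx = keep)
  attr(out, "provenance") <- unique(c(attr(g, "provenance"), "ld_pruned"))
  out
}
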