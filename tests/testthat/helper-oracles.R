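# Independent brute-force oracles used to validate the package's estimators.
# These are deliberately naive transcriptions (scalar loops, full
# enumeration) kept separate from the implementations they check.

# Hardy-Weinberg exact test by full enumeration of genotype tables
# conditional on the allele counts, using plain factorials.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- sapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
          lfactorial(2 * n))
  })
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-10)])
}

# KING-robust kinship for one pair, scalar loop.
king_oracle <- function(xa, xb) {
  nhh <- nopp <- ha <- hb <- 0
  for (l in seq_along(xa)) {
    if (is.na(xa[l]) || is.na(xb[l])) next
    if (xa[l] == 1 && xb[l] == 1) nhh <- nhh + 1
    if (abs(xa[l] - xb[l]) == 2) nopp <- nopp + 1
    if (xa[l] == 1) ha <- ha + 1
    if (xb[l] == 1) hb <- hb + 1
  }
  if (ha + hb == 0) return(NA_real_)
  (nhh - 2 * nopp) / (ha + hb)
}

# Weir & Cockerham (1984) per-locus F_ST for two groups of diploid dosages,
# literal scalar transcription of the published formulas.
wc_oracle <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  r <- 2
  n1 <- length(x1); n2 <- length(x2)
  p1 <- mean(x1) / 2; p2 <- mean(x2) / 2
  h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
    ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc,
    fst = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

# Brute-force ROH scanner for one sample on one chromosome: explicit window
# loops, then explicit run assembly and filtering.
roh_oracle <- function(x, pos, params) {
  L <- length(x); W <- params$window_snps
  if (L < W) return(NULL)
  nW <- L - W + 1
  win_ok <- logical(nW)
  for (w in seq_len(nW)) {
    seg <- x[w:(w + W - 1)]
    win_ok[w] <- sum(seg == 1, na.rm = TRUE) <= params$window_het &&
      sum(is.na(seg)) <= params$window_missing
  }
  cand <- logical(L)
  for (s in seq_len(L)) {
    ws <- max(1, s - W + 1):min(s, nW)
    cand[s] <- mean(win_ok[ws]) >= params$hit_threshold
  }
  segs <- list()
  s <- 1
  while (s <= L) {
    if (!cand[s]) { s <- s + 1; next }
    e <- s
    while (e < L && cand[e + 1] &&
           (pos[e + 1] - pos[e]) <= params$max_gap_kb * 1000) e <- e + 1
    n <- e - s + 1
    len_kb <- (pos[e] - pos[s]) / 1000
    if (n >= params$min_snps && len_kb >= params$min_length_kb &&
        len_kb / n <= params$max_density_kb_per_snp)
      segs[[length(segs) + 1]] <- data.frame(start_bp = pos[s], end_bp = pos[e],
                                             n_snps = n, length_kb = len_kb)
    s <- e + 1
  }
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

# Convex hull area by gift wrapping + shoelace, independent of chull().
hull_area_oracle <- function(x, y) {
  n <- length(x)
  start <- which.min(x)
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- setdiff(seq_len(n), cur)
    nxt <- cand[1]
    for (k in cand[-1]) {
      cr <- (x[nxt] - x[cur]) * (y[k] - y[cur]) -
        (y[nxt] - y[cur]) * (x[k] - x[cur])
      d_nxt <- (x[nxt] - x[cur])^2 + (y[nxt] - y[cur])^2
      d_k <- (x[k] - x[cur])^2 + (y[k] - y[cur])^2
      if (cr < 0 || (cr == 0 && d_k > d_nxt)) nxt <- k
    }
    if (nxt == start) break
    hull <- c(hull, nxt)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  hx <- x[hull]; hy <- y[hull]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}
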