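test_that("per-SNP Weir-Cockerham F_ST hits the textbook limits", {
  # fixed difference, equal sample sizes
  g <- make_geno(rbind(matrix(2, 10, 3), matrix(0, 10, 3)))
  fs <- fst_per_snp(g, rep(c("a", "b"), each = 10))
  expect_equal(fs$fst, rep(1, 3))
  # identical frequencies: near zero, possibly slightly negative
  set.seed(61)
  d <- draw_pool(400, runif(300, 0.3, 0.7))
  fs2 <- fst_per_snp(make_geno(d), rep(c("a", "b"), each = 200))
  expect_lt(abs(global_fst(fs2)), 0.005)
  # monomorphic in both: components zero, estimate undefined
  mono <- make_geno(cbind(rep(2, 20), rbinom(20, 2, .5)))
  fm <- fst_per_snp(mono, rep(c("a", "b"), each = 10))
  expect_true(is.na(fm$fst[1]))
  expect_equal(fm$a[1] + fm$b[1] + fm$c[1], 0)
})

test_that("the vectorised estimator matches the scalar 1984 oracle", {
  # a hand-specified HWE-balanced table: n1 = n2 = 10, p1 = 0.7, p2 = 0.3
  x1 <- c(rep(2, 5), rep(1, 4), rep(0, 1))   # p = 0.7
  x2 <- c(rep(2, 1), rep(1, 4), rep(0, 5))   # p = 0.3
  g <- make_geno(cbind(c(x1, x2)))
  fs <- fst_per_snp(g, rep(c("a", "b"), each = 10))
  o <- wc_oracle(x1, x2)
  expect_equal(fs$fst, unname(o["fst"]), tolerance = 1e-12)
  expect_equal(fs$a, unname(o["a"]), tolerance = 1e-12)
  set.seed(62)
  for (k in 1:100) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    x1 <- rbinom(n1, 2, runif(1, 0.05, 0.95))
    x2 <- rbinom(n2, 2, runif(1, 0.05, 0.95))
    g <- make_geno(cbind(c(x1, x2)))
    fs <- fst_per_snp(g, rep(c("a", "b"), c(n1, n2)))
    o <- wc_oracle(x1, x2)
    if (is.na(o["fst"])) expect_true(is.na(fs$fst)) else
      expect_equal(fs$fst, unname(o["fst"]), tolerance = 1e-12)
  }
})

test_that("windowed F_ST aggregates by ratio of sums and keeps empty tiles", {
  set.seed(63)
  p <- draw_founder_freqs(60)
  d <- rbind(draw_pool(40, p), draw_pool(40, balding_nichols_freqs(p, 0.05)))
  g <- make_geno(d, pos = c(seq(1000, 49000, length.out = 50),
                            seq(150001, 199000, length.out = 10)))
  fs <- fst_per_snp(g, rep(c("a", "b"), each = 40))
  w <- window_fst(fs, window_bp = 50000)
  expect_equal(w$n_snps, c(50L, 0L, 0L, 10L))
  expect_true(is.na(w$fst_weighted[2]))
  # a window spanning everything equals the global ratio of sums
  w1 <- window_fst(fs, window_bp = 2e5)
  expect_equal(w1$fst_weighted[1], global_fst(fs), tolerance = 1e-12)
  # smaller windows fluctuate more around the global value
  set.seed(64)
  p2 <- draw_founder_freqs(600)
  d2 <- rbind(draw_pool(50, p2), draw_pool(50, balding_nichols_freqs(p2, 0.05)))
  g2 <- make_geno(d2, pos = seq_len(600) * 1000)
  fs2 <- fst_per_snp(g2, rep(c("a", "b"), each = 50))
  small <- window_fst(fs2, window_bp = 10000)   # 10 SNPs per window
  big <- window_fst(fs2, window_bp = 100000)    # 100 SNPs per window
  expect_gt(var(small$fst_weighted, na.rm = TRUE),
            var(big$fst_weighted, na.rm = TRUE))
})

test_that("Hudson cross-check agrees with Weir-Cockerham on balanced data", {
  set.seed(65)
  p <- draw_founder_freqs(4000)
  d1 <- draw_pool(100, p)
  d2 <- draw_pool(100, balding_nichols_freqs(p, 0.05))
  g <- make_geno(rbind(d1, d2))
  wc <- global_fst(fst_per_snp(g, rep(c("a", "b"), each = 100)))
  hu <- hudson_fst(colMeans(d1) / 2, rep(200, 4000),
                   colMeans(d2) / 2, rep(200, 4000))
  expect_lt(abs(wc - hu), 0.005)
})

test_that("MDS-extreme subsets are the most distinct and stay unrelated", {
  mk_report <- function(n = 60) {
    set.seed(66)
    lab <- rep(c("local", "immigrant"), each = n / 2)
    mds <- cbind(MDS1 = rnorm(n) + (lab == "immigrant") * 2,
                 MDS2 = rnorm(n) - (lab == "local") * 2)
    structure(list(mds = scale(mds, scale = FALSE), labels = factor(lab),
                   sample_ids = paste0("s", 1:n)),
              class = "classifier_report")
  }
  rep <- mk_report()
  sub <- extreme_subsets(rep, k = 5)
  expect_length(sub$top_immigrants, 5)
  expect_length(intersect(sub$top_immigrants, sub$top_locals), 0)
  # k = 1 picks the single most extreme individual toward the group side
  one <- extreme_subsets(rep, k = 1)
  imm <- rep$labels == "immigrant"
  expect_identical(one$top_immigrants,
                   rep$sample_ids[imm][which.max(rep$mds[imm, 1])])
  expect_error(extreme_subsets(rep, k = 500), "exceeds")
})

test_that("selecting classifier-extreme subsets inflates F_ST", {
  set.seed(67)
  p <- draw_founder_freqs(600)
  d <- rbind(draw_pool(70, p), draw_pool(70, balding_nichols_freqs(p, 0.02)))
  status <- rep(c("local", "immigrant"), each = 70)
  g <- make_geno(d, status = status)
  pc <- suppressWarnings(geno_pca(g, 15))
  rep <- rf_ensemble(pc$scores, status,
                     classifier_config(n_repeats = 2, n_forests = 5,
                                       trees_per_forest = 200, seed = 3L))
  rep$sample_ids <- g$samples$id[rep$sample_index]
  sub <- extreme_subsets(rep, k = 25)
  fs_all <- global_fst(fst_per_snp(g, status))
  both <- c(sub$top_immigrants, sub$top_locals)
  gs <- subset_geno(g, sample_idx = g$samples$id %in% both)
  fs_sub <- global_fst(fst_per_snp(gs, gs$samples$status))
  expect_gte(fs_sub, fs_all)
  # kinship screen reports within-subset maxima when supplied
  kg <- king_robust(g, classify = FALSE)
  sub2 <- extreme_subsets(rep, k = 25, kinship = kg)
  expect_true(is.finite(sub2$max_phi_immigrants))
  expect_true(is.finite(sub2$max_phi_locals))
})
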