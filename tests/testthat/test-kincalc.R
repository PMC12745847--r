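test_that("method-of-moments IBD recovers canonical relationships", {
  set.seed(21)
  L <- 3000; n <- 60
  p <- runif(L, 0.1, 0.9)
  hap <- function(k) matrix(rbinom(k * L, 1, rep(p, each = k)), k)
  pa1 <- hap(n); pa2 <- hap(n); pb1 <- hap(n); pb2 <- hap(n)
  pick <- function(h1, h2) {
    s <- matrix(rbinom(n * L, 1, .5), n); h1 * (1 - s) + h2 * s
  }
  kid <- pick(pa1, pa2) + pick(pb1, pb2)
  g <- make_geno(rbind(pa1 + pa2, kid),
                 ids = c(paste0("p", 1:n), paste0("k", 1:n)))
  ib <- mom_ibd(g)
  po <- grepl("^p", ib$id_a) & ib$id_b == sub("p", "k", ib$id_a)
  expect_equal(sum(po), n)
  expect_lt(abs(mean(ib$pi_hat[po]) - 0.5), 0.02)
  unrel <- grepl("^p", ib$id_a) & grepl("^p", ib$id_b)
  expect_lt(abs(mean(ib$pi_raw[unrel])), 0.01)
  # clamping to [0, 1] leaves a small positive noise floor at this locus count
  expect_lt(mean(ib$pi_hat[unrel]), 0.03)
  # duplicated sample against itself
  gdup <- make_geno(rbind(kid[1, ], kid[1, ]), ids = c("a", "b"))
  expect_gt(mom_ibd(gdup)$pi_hat, 0.99)
  # symmetric in locus order
  ib2 <- mom_ibd(subset_geno(g, loci_idx = sample(L)))
  expect_equal(ib2$pi_hat, ib$pi_hat, tolerance = 1e-12)
})

test_that("pairs with few informative loci are flagged low-confidence", {
  set.seed(4)
  g <- make_geno(draw_pool(6, runif(30, .3, .7)))
  ib <- mom_ibd(g, min_loci = 50)
  expect_true(all(ib$low_conf))
})

test_that("KING-robust kinship matches hand-counted tables and limits", {
  # identical genotypes: phi = 0.5
  x <- c(0, 1, 2, 1, 0, 1, 2, 1)
  g <- make_geno(rbind(x, x), ids = c("a", "b"))
  expect_equal(king_robust(g, classify = FALSE)$phi, 0.5)
  # hand-counted table: N_AaAa = 2, N_AA,aa = 1, N_Aa(a) = N_Aa(b) = 4
  a <- c(1, 1, 1, 1, 0, 0, 2)
  b <- c(1, 1, 0, 0, 1, 1, 0)
  gh <- make_geno(rbind(a, b), ids = c("a", "b"))
  expect_equal(king_robust(gh, classify = FALSE)$phi, (2 - 2 * 1) / (4 + 4))
  # zero denominator flagged
  g0 <- make_geno(rbind(c(0, 2, 0), c(0, 2, 2)), ids = c("a", "b"))
  k0 <- king_robust(g0, classify = FALSE)
  expect_true(k0$undefined)
  expect_true(is.na(k0$phi))
})

test_that("samples from diverged pools have negative KING kinship", {
  set.seed(9)
  p <- draw_founder_freqs(3000)
  d <- rbind(draw_pool(40, balding_nichols_freqs(p, 0.1)),
             draw_pool(40, balding_nichols_freqs(p, 0.1)))
  g <- make_geno(d, ids = paste0("s", 1:80))
  kg <- king_robust(g, classify = FALSE)
  cross <- (match(kg$id_a, g$samples$id) <= 40) !=
    (match(kg$id_b, g$samples$id) <= 40)
  expect_lt(mean(kg$phi[cross]), 0)
})

test_that("kinship degrees follow the KING cutoffs and classify full sibs", {
  expect_identical(as.character(classify_degree(c(0.4, 0.25, 0.12, 0.05, 0.01))),
                   c("duplicate", "first", "second", "third", "unrelated"))
  set.seed(10)
  L <- 5000; n <- 60
  p <- runif(L, 0.1, 0.9)
  hap <- function(k) matrix(rbinom(k * L, 1, rep(p, each = k)), k)
  pa1 <- hap(n); pa2 <- hap(n); pb1 <- hap(n); pb2 <- hap(n)
  pick <- function(h1, h2) {
    s <- matrix(rbinom(n * L, 1, .5), n); h1 * (1 - s) + h2 * s
  }
  sib1 <- pick(pa1, pa2) + pick(pb1, pb2)
  sib2 <- pick(pa1, pa2) + pick(pb1, pb2)
  g <- make_geno(rbind(sib1, sib2),
                 ids = c(paste0("x", 1:n), paste0("y", 1:n)))
  kg <- king_robust(g)
  sibs <- grepl("^x", kg$id_a) & kg$id_b == sub("x", "y", kg$id_a)
  expect_gte(mean(kg$degree[sibs] == "first"), 0.95)
})

test_that("KING kinship matches the scalar oracle pair by pair", {
  set.seed(33)
  d <- draw_pool(8, runif(400, 0.05, 0.95))
  d[sample(length(d), 60)] <- NA
  g <- make_geno(d)
  kg <- king_robust(g, classify = FALSE)
  for (r in seq_len(nrow(kg))) {
    xa <- d[match(kg$id_a[r], g$samples$id), ]
    xb <- d[match(kg$id_b[r], g$samples$id), ]
    expect_equal(kg$phi[r], king_oracle(xa, xb), tolerance = 1e-12)
  }
})

test_that("ROH detection matches the brute-force scanner", {
  params <- roh_params(window_snps = 10, window_het = 1, window_missing = 2,
                       min_snps = 20, min_length_kb = 50,
                       max_density_kb_per_snp = 50, max_gap_kb = 100)
  set.seed(14)
  for (k in 1:25) {
    L <- 400
    pos <- sort(runif(L, 1, 2e6))
    x <- rbinom(L, 2, runif(1, 0.3, 0.7))
    # plant a homozygous run
    st <- sample(1:(L - 120), 1)
    x[st:(st + sample(60:120, 1))] <- sample(c(0, 2), 1)
    x[sample(L, 8)] <- NA
    g <- make_geno(rbind(x), chrom = "1", pos = pos, ids = "s1")
    got <- detect_roh(g, params)
    want <- roh_oracle(x, pos, params)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$end_bp, want$end_bp)
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("ROH calls honour the constructed-run fixture and het limits", {
  # 120 homozygous SNPs spanning ~1.2 Mb with one embedded heterozygote
  set.seed(6)
  L <- 400
  pos <- c(sort(runif(140, 1, 1.4e6)), seq(1.4e6, 2.6e6, length.out = 120),
           sort(runif(140, 2.6e6, 4e6)))
  x <- rbinom(L, 2, 0.5)
  run <- 141:260
  x[run] <- 0
  x[200] <- 1
  g <- make_geno(rbind(x), pos = pos, ids = "s1")
  segs <- detect_roh(g, roh_params(min_snps = 100, min_length_kb = 1000))
  expect_equal(nrow(segs), 1)
  expect_lte(segs$start_bp, pos[145])
  expect_gte(segs$end_bp, pos[256])
  # a fully heterozygous genome has no runs
  gh <- make_geno(matrix(1L, 1, L), pos = pos, ids = "h")
  expect_equal(nrow(detect_roh(gh)), 0)
})

test_that("ROH refuses MAF-filtered or pruned input unless overridden", {
  set.seed(2)
  g <- make_geno(draw_pool(30, runif(300, .2, .8)))
  gq <- apply_qc(g)$genotypes
  expect_error(detect_roh(gq), "MAF-filtered")
  expect_no_error(detect_roh(gq, allow_filtered = TRUE))
})

test_that("offspring of full-sib matings carry about a quarter of the genome in ROH", {
  fix <- inbred_offspring(n_off = 20)
  segs <- detect_roh(fix$genotypes)
  sm <- roh_summary(segs, fix$genotypes$samples$id, genome_kb = fix$genome_kb)
  expect_lt(abs(mean(sm$f_roh) - 0.25), 0.05)
})

test_that("copy-aware Z relatedness reflects ZW transmission", {
  set.seed(15)
  L <- 2000
  p <- runif(L, 0.2, 0.8)
  mum_z <- rbinom(L, 1, p)
  dad_z1 <- rbinom(L, 1, p); dad_z2 <- rbinom(L, 1, p)
  mix <- rbinom(L, 1, .5); mix2 <- rbinom(L, 1, .5)
  son <- mum_z + (dad_z1 * mix + dad_z2 * (1 - mix))
  daughter <- dad_z1 * mix2 + dad_z2 * (1 - mix2)
  # background individuals so sample allele frequencies are well estimated
  bg_m <- matrix(rbinom(20 * L, 1, rep(p, 20)), 20, byrow = TRUE) +
    matrix(rbinom(20 * L, 1, rep(p, 20)), 20, byrow = TRUE)
  bg_f <- matrix(rbinom(20 * L, 1, rep(p, 20)), 20, byrow = TRUE)
  d <- rbind(son, mum_z, daughter, rbinom(L, 1, p), bg_m, bg_f)
  g <- geno_matrix(d, data.frame(chrom = "Z", pos_bp = seq_len(L) * 1000),
                   data.frame(id = c("son", "mum", "dau", "unrel",
                                     paste0("m", 1:20), paste0("f", 1:20)),
                              sex = c("M", "F", "F", "F",
                                      rep("M", 20), rep("F", 20))))
  zr <- z_relatedness(g)
  get <- function(a, b) zr$r[(zr$id_a == a & zr$id_b == b) |
                               (zr$id_a == b & zr$id_b == a)]
  expect_lt(abs(get("son", "mum") - 1), 0.1)   # son carries mum's whole Z
  expect_lt(abs(get("mum", "unrel")), 0.1)
  expect_gt(get("son", "dau"), 0.3)            # paternal-gamete sharing
  # the diploid-toolchain dialect attenuates relatedness involving females
  zp <- z_pair_ibd(g, dialect = "plink_diploid")
  cp <- z_pair_ibd(g, dialect = "copy_aware")
  ms_p <- zp$pi_hat[(zp$id_a == "son" & zp$id_b == "mum") |
                      (zp$id_a == "mum" & zp$id_b == "son")]
  ms_c <- cp$pi_hat[(cp$id_a == "son" & cp$id_b == "mum") |
                      (cp$id_a == "mum" & cp$id_b == "son")]
  expect_lt(ms_p, ms_c)
})
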