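test_that("PCA separates diverged pools and duplicates score identically", {
  set.seed(31)
  p <- draw_founder_freqs(800)
  d <- rbind(draw_pool(60, balding_nichols_freqs(p, 0.2)),
             draw_pool(60, balding_nichols_freqs(p, 0.2)))
  d <- rbind(d, d[1, ])  # duplicate of sample 1
  g <- make_geno(d, ids = paste0("s", 1:121))
  pc <- suppressWarnings(geno_pca(g, n_pc = 4))
  grp <- rep(c(1, 2), c(60, 61))
  sep <- abs(mean(pc$scores[grp == 1, 1]) - mean(pc$scores[grp == 2, 1]))
  within <- mean(c(sd(pc$scores[grp == 1, 1]), sd(pc$scores[grp == 2, 1])))
  expect_gt(sep / within, 4)
  expect_gt(pc$varexp[1] / pc$varexp[2], 3)
  expect_equal(pc$scores[1, ], pc$scores[121, ], tolerance = 1e-8)
  expect_true(all(diff(pc$varexp) <= 1e-12))
  expect_lte(sum(pc$varexp), 1 + 1e-8)
})

test_that("a panmictic pool shows no leading axis beyond the permutation null", {
  set.seed(32)
  d <- draw_pool(80, runif(500, 0.2, 0.8))
  g <- make_geno(d)
  v1 <- geno_pca(g, 2)$varexp[1]
  null_v1 <- replicate(3, {
    dp <- apply(d, 2, sample)
    geno_pca(make_geno(dp), 2)$varexp[1]
  })
  expect_lt(v1, 1.25 * mean(null_v1))
})

test_that("pair annotation computes breeding and natal distances by the rules", {
  loc <- data.frame(box_id = 1:4, x = c(0, 300, 0, 1000),
                    y = c(0, 400, 50, 0))
  samples <- data.frame(id = c("a", "b", "c", "d", "e"),
                        sex = c("M", "F", "M", "F", "M"),
                        status = c("local", "local", "local", "immigrant", "local"),
                        natal_box = c(1, 2, 1, NA, 3))
  breeding <- data.frame(id = c("a", "b", "c", "d", "e"),
                         year = c(1, 1, 1, 2, 5),
                         box_id = c(1, 2, 1, 2, 3))
  pairs <- data.frame(id_a = c("a", "a", "c", "a", "a"),
                      id_b = c("b", "c", "d", "e", "d"),
                      pi_hat = 0.1)
  pt <- pair_table(pairs, samples, breeding, loc)
  expect_equal(pt$breeding_distance_m[1], 500)       # 3-4-5 same year
  expect_equal(pt$breeding_distance_m[2], 0)         # same box same year
  expect_equal(pt$breeding_distance_m[3], 500)       # one-year gap, min rule
  expect_true(is.na(pt$breeding_distance_m[4]))      # 4-year gap excluded
  expect_equal(attr(pt, "n_excluded"), 1)
  expect_equal(pt$natal_distance_m[1], 500)
  expect_true(is.na(pt$natal_distance_m[3]))         # immigrant in pair
  expect_identical(pt$pair_type[3], "local-immigrant")
  expect_identical(pt$sex_pair[1], "MF")
  expect_identical(pt$sex_pair[2], "MM")
})

test_that("kin stripping filters by SNP degree and by social pedigree", {
  pairs <- data.frame(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                      pi_hat = 0.2,
                      degree = factor(c("first", "third", "unrelated"),
                                      levels = levels(classify_degree(0.1))))
  expect_identical(strip_kin(pairs, "none"), pairs)
  expect_equal(nrow(strip_kin(pairs, "no_first")), 2)
  expect_equal(nrow(strip_kin(pairs, "distant_only")), 1)
  all_first <- pairs; all_first$degree[] <- "first"
  expect_equal(nrow(strip_kin(all_first, "no_first")), 0)
  # social pedigree: a is b's dam; b and c are full sibs; c and d half sibs
  ped <- data.frame(id = c("a", "x", "b", "c", "d"),
                    dam = c(NA, NA, "a", "a", "a"),
                    sire = c(NA, NA, "x", "x", "y"))
  sp <- data.frame(id_a = c("a", "b", "c"), id_b = c("b", "c", "d"),
                   pi_hat = 0.2)
  out <- strip_kin(sp, "no_first", source = "social_pedigree", pedigree = ped)
  expect_identical(paste(out$id_a, out$id_b), "c d")   # PO and FS removed
  out2 <- strip_kin(sp, "no_first", source = "social_pedigree", pedigree = ped,
                    drop_half_sibs = TRUE)
  expect_equal(nrow(out2), 0)
})

test_that("decay curves fall with distance under kin clustering and stay flat without", {
  set.seed(34)
  n <- 2500
  d <- runif(n, 0, 4000)
  pairs <- data.frame(id_a = paste0("a", 1:n), id_b = paste0("b", 1:n),
                      pi_hat = pmax(0, 0.05 * exp(-d / 800) +
                                      rnorm(n, 0, 0.01)),
                      breeding_distance_m = d)
  cv <- decay_curve(pairs, n_boot = 60)
  expect_true(all(diff(cv$mean[1:5]) < 0))
  expect_lt(stats::cor(cv$mid, cv$mean, method = "spearman"), -0.9)
  expect_true(all(cv$lo <= cv$mean & cv$mean <= cv$hi))
  expect_equal(sum(cv$n_pairs), n)
  flat <- pairs; flat$pi_hat <- pmax(0, rnorm(n, 0.02, 0.01))
  cf <- decay_curve(flat, n_boot = 60)
  expect_gt(stats::cor(cf$mid, cf$mean, method = "spearman"), -0.6)
  expect_lt(abs(curve_slope(cf)), abs(curve_slope(cv)))
  # empty bins are reported as gaps
  gap <- pairs[pairs$breeding_distance_m < 1000 |
                 pairs$breeding_distance_m > 3000, ]
  cg <- decay_curve(gap, n_boot = 0)
  expect_true(any(is.na(cg$mean) & cg$n_pairs == 0))
})

test_that("bootstrap intervals widen as pairs become scarce", {
  set.seed(35)
  make_pairs <- function(n) {
    ids <- paste0("i", seq_len(ceiling(sqrt(n) * 2)))
    pick <- t(replicate(n, sample(ids, 2)))
    data.frame(id_a = pick[, 1], id_b = pick[, 2],
               pi_hat = pmax(0, rnorm(n, 0.03, 0.02)),
               breeding_distance_m = runif(n, 0, 500))
  }
  wide <- decay_curve(make_pairs(60), breaks = c(0, 500), n_boot = 120)
  narrow <- decay_curve(make_pairs(2000), breaks = c(0, 500), n_boot = 120)
  expect_gt(wide$hi - wide$lo, narrow$hi - narrow$lo)
})

test_that("the spline fit recovers a noiseless linear decline exactly", {
  set.seed(36)
  n <- 1200
  d <- runif(n, 0, 4000)
  v <- 0.1 - 0.04 * (d / sd(d))
  pairs <- data.frame(id_a = paste0("a", 1:n), id_b = paste0("b", 1:n),
                      pi_hat = v, breeding_distance_m = d,
                      pair_type = "local-local")
  fit <- stratified_fit(pairs, min_pairs = 100, n_boot = 0)
  expect_equal(fit$beta_std, -0.04, tolerance = 1e-6)
  # permuted distances: the bootstrap CI covers zero
  perm <- pairs
  perm$pi_hat <- pmax(0, rnorm(n, 0.03, 0.02))
  fitp <- stratified_fit(perm, min_pairs = 100, n_boot = 80)
  expect_lte(fitp$ci_lo, 0)
  expect_gte(fitp$ci_hi, 0)
  expect_error(stratified_fit(transform(pairs, breeding_distance_m = 100),
                              min_pairs = 100, n_boot = 0), "degenerate")
})

test_that("the autosome-Z sex-pair contrast produces the six labelled curves", {
  sim <- small_sim()
  g <- sim_genotypes(sim)
  sp <- split_datasets(g)
  ibd <- mom_ibd(sp$autosomal)
  pa <- pair_table(ibd, g$samples, breeding_records(sim), sim$map)
  zp <- z_pair_ibd(sp$z_only)
  pz <- pair_table(zp, g$samples, breeding_records(sim), sim$map)
  cs <- chrom_sex_contrast(pa, pz, n_boot = 0)
  expect_named(cs, c("auto_MM", "z_MM", "auto_MF", "z_MF", "auto_FF", "z_FF"))
  expect_s3_class(cs$z_MM, "decay_curve")
  expect_setequal(unique(pz$estimator[pz$sex_pair == "MM"]), "mom_diploid")
  expect_setequal(unique(pz$estimator[pz$sex_pair != "MM"]), "copy_aware")
})
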