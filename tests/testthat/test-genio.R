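test_that("a handwritten VCF parses into the expected dosage matrix", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb\tc",
    "1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tsnp2\tA\tG\t.\tPASS\t.\tGT\t./.\t1|1\t0/1"), f)
  g <- read_genotypes(f, "vcf")
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(unname(g$dosage[, 1]), c(0, 1, 2))
  expect_equal(unname(g$dosage[, 2]), c(NA, 2, 1))
})

test_that("VCF export/import round-trips the simulator's genotypes", {
  sim <- small_sim()
  g <- sim_genotypes(sim)
  g <- subset_geno(g, loci_idx = c(1:120, which(g$loci$is_z)[1:40]),
                   sample_idx = 1:30)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, f)
  # female Z records carry haploid GT fields
  lines <- readLines(f)
  zline <- lines[grep("^Z\t", lines)[1]]
  fem_col <- 9 + which(g$samples$sex == "F")[1]
  expect_false(grepl("/", strsplit(zline, "\t")[[1]][fem_col]))
  g2 <- read_genotypes(f, "vcf")
  expect_equal(unname(g2$dosage), unname(g$dosage))
  expect_identical(g2$samples$sex, g$samples$sex)
})

test_that("PLINK text round-trips, with the female-Z duplication undone", {
  sim <- small_sim()
  g <- sim_genotypes(sim)
  g <- subset_geno(g, loci_idx = c(1:100, which(g$loci$is_z)[1:30]),
                   sample_idx = 1:25)
  g$dosage[2, 5] <- NA  # exercise the "0 0" missing convention
  base <- file.path(withr::local_tempdir(), "geno")
  write_plink(g, base)
  expect_equal(length(readLines(paste0(base, ".map"))), ncol(g$dosage))
  g2 <- read_genotypes(paste0(base, ".ped"), "plink_text")
  expect_equal(unname(g2$dosage), unname(g$dosage))
})

test_that("malformed PLINK records are reported with their line number", {
  dir <- withr::local_tempdir()
  writeLines(c("1 snp1 0 100", "1 snp2 0 200"), file.path(dir, "bad.map"))
  writeLines(c("FAM a 0 0 1 -9 A A A G",
               "FAM b 0 0 2 -9 A A"), file.path(dir, "bad.ped"))
  expect_error(read_genotypes(file.path(dir, "bad.ped"), "plink_text"),
               "line 2")
})

test_that("sample metadata joins from a sidecar table", {
  sim <- small_sim()
  g <- sim_genotypes(sim)
  gs <- subset_geno(g, loci_idx = 1:50, sample_idx = 1:10)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gs, f)
  meta <- gs$samples[, c("id", "status")]
  g2 <- read_genotypes(f, "vcf", samples = meta)
  expect_identical(g2$samples$status, gs$samples$status)
})

test_that("QC drops loci by call rate, MAF and Hardy-Weinberg", {
  set.seed(42)
  n <- 100
  p <- runif(37, 0.2, 0.8)
  d <- draw_pool(n, p)
  # locus 38: MAF 0.04; locus 39: HWE catastrophe (50, 0, 50); locus 40: low call rate
  d <- cbind(d, rbinom(n, 2, 0.04))
  d <- cbind(d, rep(c(0, 2), each = 50))
  low_cr <- rbinom(n, 2, 0.5); low_cr[1:10] <- NA
  d <- cbind(d, low_cr)
  g <- make_geno(d)
  res <- apply_qc(g, qc_params())
  kept <- res$genotypes$loci$snp_id
  expect_false(any(c("snp00038", "snp00039", "snp00040") %in% kept))
  expect_gte(res$report$n_fail_maf, 1)
  expect_gte(res$report$n_fail_hwe, 1)
  expect_gte(res$report$n_fail_call_rate, 1)
  expect_equal(res$report$n_removed + res$report$n_kept, res$report$n_loci_in)
  # order independence across loci
  perm <- sample(ncol(d))
  res2 <- apply_qc(subset_geno(g, loci_idx = perm), qc_params())
  expect_setequal(res2$genotypes$loci$snp_id, kept)
})

test_that("a clean common locus is retained and empty results are flagged", {
  set.seed(1)
  d <- cbind(rbinom(200, 2, 0.5))
  res <- apply_qc(make_geno(cbind(d, d[sample(200)], rbinom(200, 2, 0.4))))
  expect_equal(res$report$n_kept, 3)
  allbad <- make_geno(matrix(rbinom(400, 2, 0.01), 100))
  res2 <- apply_qc(allbad)
  expect_true(res2$report$all_removed)
  expect_equal(ncol(res2$genotypes$dosage), 0)
})

test_that("the Hardy-Weinberg exact test matches full enumeration", {
  expect_equal(hwe_exact_p(25, 50, 25), 1, tolerance = 1e-9)
  expect_equal(hwe_exact_p(1, 0, 1), hwe_oracle(1, 0, 1), tolerance = 1e-12)
  expect_lt(hwe_exact_p(50, 0, 50), 1e-4)
  expect_error(hwe_exact_p(0, 0, 0), "at least one")
  set.seed(8)
  for (k in 1:60) {
    cts <- rand_geno_counts(30)
    p <- hwe_exact_p(cts[1], cts[2], cts[3])
    expect_gte(p, 0); expect_lte(p, 1)
    expect_equal(p, hwe_oracle(cts[1], cts[2], cts[3]), tolerance = 1e-10)
  }
})

test_that("LD pruning drops the later duplicate and spares independent loci", {
  set.seed(3)
  n <- 500
  p <- runif(150, 0.2, 0.8)
  d <- draw_pool(n, p)
  dup <- cbind(d[, 1])                 # duplicate of locus 1, 1 kb downstream
  d2 <- cbind(d[, 1], dup, d[, -1])
  pos <- c(1000, 2000, seq(10000, by = 3000, length.out = 149))
  g <- make_geno(d2, pos = pos)
  keep <- ld_prune(g, ld_prune_params())
  expect_true(keep[1]); expect_false(keep[2])
  expect_gte(mean(keep[-2]), 0.99)
  # idempotence
  gp <- apply_ld_prune(g)
  expect_true(all(ld_prune(gp)))
})

test_that("dataset splitting is disjoint and exhaustive", {
  d <- draw_pool(20, runif(30, .2, .8))
  g <- make_geno(d, chrom = rep(c("1", "1A", "Z"), each = 10))
  sp <- split_datasets(g, exclude = "1A")
  expect_equal(ncol(sp$autosomal$dosage), 10)
  expect_equal(ncol(sp$z_only$dosage), 10)
  expect_equal(sp$n_excluded, 10)
  expect_false(any(sp$autosomal$loci$chrom == "1A"))
  expect_equal(ncol(sp$autosomal$dosage) + ncol(sp$z_only$dosage) +
                 sp$n_excluded, 30)
  expect_warning(split_datasets(make_geno(d, chrom = "2")), "no Z")
})
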