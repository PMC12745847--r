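test_that("nestbox maps report exact woodland geometry", {
  sq <- nestbox_map(data.frame(box_id = 1:4,
                               x = c(0, 100, 0, 100), y = c(0, 0, 100, 100)))
  expect_equal(woodland_extent(sq), 100 * sqrt(2))
  expect_error(nestbox_map(data.frame(box_id = c(1, 1), x = 0:1, y = 0:1)),
               "unique")
  expect_error(nestbox_map(data.frame(box_id = 1, x = 0, y = 0)), "2 boxes")
})

test_that("generated landscapes hit the configured extent and are seeded", {
  cfg <- sim_config(n_boxes = 1019, extent_m = 4000, seed = 7L,
                    track_genotypes = FALSE)
  m1 <- build_landscape(cfg)
  expect_equal(nrow(m1), 1019)
  expect_lt(abs(woodland_extent(m1) - 4000) / 4000, 0.05)
  m2 <- build_landscape(cfg)
  expect_identical(m1$x, m2$x)
  expect_identical(m1$y, m2$y)
  expect_error(sim_config(extent_m = -1), "positive")
  expect_error(sim_config(occupancy = 1.4), "probability")
  expect_error(sim_config(disp_median_male_m = 900, disp_median_female_m = 500),
               "dispersal")
})

test_that("meiosis obeys Mendelian transmission", {
  L <- 200
  chrom <- rep("1", L); rel <- seq_len(L) / L
  gam <- meiosis_gamete(rep(0L, L), rep(0L, L), chrom, rel, c("1" = 1))
  expect_true(all(gam == 0))
  # 0/0 x 1/1 parents -> every offspring heterozygous
  kid <- meiosis_gamete(rep(0L, L), rep(0L, L), chrom, rel, c("1" = 1)) +
    meiosis_gamete(rep(1L, L), rep(1L, L), chrom, rel, c("1" = 1))
  expect_true(all(kid == 1))
  # recombination mixes the two haplotypes
  set.seed(2)
  mix <- meiosis_gamete(rep(0L, L), rep(1L, L), chrom, rel, c("1" = 5))
  expect_true(any(mix == 0) && any(mix == 1))
})

test_that("simulated offspring are Mendelian-consistent with genetic parents", {
  sim <- small_sim()
  g <- sim_genotypes(sim)
  ped <- sim$pedigree
  auto <- !g$loci$is_z
  ids <- g$samples$id
  checked <- 0
  for (i in seq_len(nrow(ped))) {
    kid <- as.character(ped$id[i])
    dam <- as.character(ped$dam[i]); sire <- as.character(ped$sire[i])
    if (!all(c(kid, dam, sire) %in% ids)) next
    dk <- g$dosage[kid, auto]; dd <- g$dosage[dam, auto]
    ds <- g$dosage[sire, auto]
    expect_false(any(abs(dk - dd) == 2, na.rm = TRUE))
    expect_false(any(abs(dk - ds) == 2, na.rm = TRUE))
    checked <- checked + 1
    if (checked >= 25) break
  }
  expect_gte(checked, 10)
})

test_that("ZW bookkeeping holds: census identity and daughters' paternal Z", {
  sim <- small_sim()
  b <- sim$breeding[sim$breeding$year == 5, ]
  sexes <- c(rep("M", nrow(b)), rep("F", nrow(b)))
  expect_identical(z_copy_fraction(sexes), 2 / 3)
  # daughters carry a single Z; female Z dosage never exceeds 1
  g <- sim_genotypes(sim)
  fem <- g$samples$sex == "F"
  expect_true(all(g$dosage[fem, g$loci$is_z] <= 1, na.rm = TRUE))
})

test_that("extra-pair paternity switches genetic but not social sires", {
  cfg0 <- sim_preset("desk", n_boxes = 60L, occupancy = 0.4, epp_rate = 0,
                     n_years = 6L, track_genotypes = FALSE, seed = 3L)
  sim0 <- run_simulation(cfg0)
  kids <- !is.na(sim0$pedigree$sire)
  expect_true(all(sim0$pedigree$sire[kids] == sim0$pedigree$social_sire[kids]))
  cfg1 <- sim_preset("desk", n_boxes = 60L, occupancy = 0.4, epp_rate = 0.5,
                     epp_radius_m = 2000, n_years = 6L,
                     track_genotypes = FALSE, seed = 3L)
  sim1 <- run_simulation(cfg1)
  kids <- !is.na(sim1$pedigree$sire)
  expect_gt(mean(sim1$pedigree$sire[kids] != sim1$pedigree$social_sire[kids]),
            0.2)
})

test_that("a collapsing population reports extinction instead of crashing", {
  cfg <- sim_preset("desk", n_boxes = 30L, adult_survival = 0,
                    recruit_prob = 0, immigration_fill = 0,
                    n_years = 10L, track_genotypes = FALSE, seed = 1L)
  sim <- run_simulation(cfg)
  expect_true(sim$extinct)
  expect_true(is.finite(sim$extinct_year))
  expect_lte(sim$extinct_year, 3)
})

test_that("runs are bit-reproducible for a fixed seed", {
  cfg <- sim_preset("desk", n_boxes = 40L, n_autosomal_snps = 120L,
                    n_z_snps = 40L, n_years = 5L, seed = 21L)
  s1 <- run_simulation(cfg); s2 <- run_simulation(cfg)
  expect_identical(s1$dosage, s2$dosage)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$census, s2$census)
})

test_that("immigrant pool divergence follows the Balding-Nichols parameter", {
  set.seed(11)
  p <- draw_founder_freqs(6000)
  expect_identical(immigrant_pool_freqs(p, 0), p)
  q <- immigrant_pool_freqs(p, 0.1)
  h1 <- draw_haplotypes(200, p); h2 <- draw_haplotypes(200, q)
  fst <- hudson_fst(colMeans(h1), rep(200, 6000), colMeans(h2), rep(200, 6000))
  expect_lt(abs(fst - 0.1), 0.02)
})

test_that("immigrants drawn from one pool are unrelated", {
  set.seed(12)
  p <- draw_founder_freqs(4000)
  q <- balding_nichols_freqs(p, 0.05)
  d <- draw_haplotypes(30, q) + draw_haplotypes(30, q)
  ib <- mom_ibd(make_geno(d))
  expect_lt(mean(ib$pi_hat), 0.02)
})

test_that("realized dispersal recovers the sex-specific kernel medians", {
  sim <- run_simulation(sim_preset("desk", track_genotypes = FALSE, seed = 5L))
  dm <- dispersal_medians(sim)
  cfg <- sim$config
  expect_lt(abs(dm$male - cfg$disp_median_male_m) / cfg$disp_median_male_m,
            0.15)
  expect_lt(abs(dm$female - cfg$disp_median_female_m) /
              cfg$disp_median_female_m, 0.15)
})

test_that("neutral runs lose diversity by drift alone, at the Wright-Fisher rate", {
  cfg <- sim_preset("neutral", n_autosomal_snps = 1200L, n_z_snps = 200L,
                    n_years = 20L, seed = 71L)
  sim <- run_simulation(cfg)
  pi0 <- z_autosome_diversity(sim, year = 1)$pi_autosome
  pi_end <- z_autosome_diversity(sim, year = 20)$pi_autosome
  # 12 pairs -> N = 24; expected retention over 19 generations
  expected <- (1 - 1 / 48)^19
  expect_lt(abs(pi_end / pi0 - expected), 0.15)
})

test_that("the desk preset keeps a stable, immigrant-rich breeding population", {
  sim <- small_sim()
  expect_false(sim$extinct)
  expect_gt(mean(sim$census$n_pairs), 0.8 * 0.4 * 150)
  fr <- realized_immigrant_fraction(sim)
  expect_gt(fr, 0.3); expect_lt(fr, 0.7)
  expect_lt(abs(generation_time(sim) - 2), 0.5)
})
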