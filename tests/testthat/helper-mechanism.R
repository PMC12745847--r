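# One replicate of the scaled-down mechanism-recovery experiment: simulate a
# full monitored woodland, genotype the breeders of a ten-year study window,
# and extract the qualitative signatures of kin-driven spatial structure.
# Problem size (5000 autosomal + 800 Z SNPs, ~1800 genotyped breeders,
# 18 years) is the desk-scale stand-in for a full SNP-chip study.
mech_replicate <- function(seed) {
  cfg <- sim_preset("desk", n_autosomal_snps = 5000L, n_z_snps = 800L,
                    n_years = 18L, max_genotyped = Inf, seed = seed)
  sim <- run_simulation(cfg)
  g <- sim_genotypes(sim)
  br <- breeding_records(sim)
  win_ids <- intersect(as.character(unique(br$id[br$year >= 7])),
                       g$samples$id)
  set.seed(seed)
  keep <- sample(win_ids, min(1800, length(win_ids)))
  gw <- subset_geno(g, sample_idx = g$samples$id %in% keep)
  qcr <- apply_qc(gw)
  sp <- split_datasets(qcr$genotypes)

  ibd <- mom_ibd(sp$autosomal)
  kg <- king_robust(sp$autosomal)
  ibd$phi <- kg$phi; ibd$degree <- kg$degree
  pairs <- pair_table(ibd, gw$samples, br, sim$map)

  s_all <- ibd_distance_slope(pairs)
  s_nofirst <- ibd_distance_slope(strip_kin(pairs, "no_first"))
  fits <- stratified_fit(pairs, min_pairs = 100, n_boot = 0)
  beta_ll <- fits$beta_per_km[fits$stratum == "local-local"]
  beta_ii <- fits$beta_per_km[fits$stratum == "immigrant-immigrant"]

  zp <- z_pair_ibd(sp$z_only, dialect = "plink_diploid")
  zp <- pair_table(zp, gw$samples, br, sim$map)
  z_mm_mean <- mean(zp$pi_hat[zp$sex_pair == "MM"], na.rm = TRUE)
  auto_mm_mean <- mean(pairs$pi_hat[pairs$sex_pair == "MM"], na.rm = TRUE)
  slope_z <- sapply(c("MM", "MF", "FF"), function(spr)
    ibd_distance_slope(zp[zp$sex_pair == spr, ]))

  sel <- select_areas(sim$map, k = 70)
  area_ids <- g$samples$id[g$samples$natal_box %in%
                             c(sel$member_boxes_a, sel$member_boxes_b)]
  ga <- subset_geno(g, sample_idx = g$samples$id %in% area_ids)
  ibd_area <- mom_ibd(subset_geno(ga, loci_idx = !ga$loci$is_z))
  lg <- lag_curve(ibd_area, sel, ga$samples, n_boot = 200)
  gen_t <- generation_time(sim)
  lag0 <- mean(c(lg$area_a$mean[1], lg$area_b$mean[1]), na.rm = TRUE)
  # renewal is complete once the slower of the two areas reaches baseline
  cross_gen <- max(lg$crossing_lag, na.rm = TRUE) / gen_t

  list(
    flatten = abs(s_nofirst) < abs(s_all),
    beta_order = beta_ll < beta_ii,
    z_over_auto = z_mm_mean > auto_mm_mean,
    z_mm_steepest = slope_z["MM"] < slope_z["MF"] &&
      slope_z["MM"] < slope_z["FF"],
    lag0_elevated = lag0 > lg$baseline,
    renewed_2_5_gen = is.finite(cross_gen) && cross_gen >= 2 && cross_gen <= 5,
    cross_gen = cross_gen
  )
}
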