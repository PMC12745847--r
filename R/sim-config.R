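#' Simulation configuration
#'
#' Builds and validates the parameter set for the forward simulator
#' ([run_simulation()]). Defaults describe a ~4 km continuous woodland with
#' ~1000 nestboxes of which roughly a third hold a breeding pair each year,
#' annual adult survival near one half (so generation time close to two
#' years), sex-biased natal dispersal (female median about 1.5 times the male
#' median, roughly 300 m more, both medians below 1 km), and an external
#' immigrant pool that supplies about half of the breeding adults.
#'
#' @param n_boxes number of nestboxes.
#' @param extent_m woodland diameter: the maximum pairwise box distance, metres.
#' @param occupancy fraction of boxes holding a breeding attempt each year.
#' @param adult_survival annual adult survival probability.
#' @param recruit_prob probability a fledgling survives to recruit locally.
#' @param clutch_size_mean mean fledged brood size (Poisson).
#' @param immigration_fill probability a vacancy left unfilled by local
#'   recruits is taken by an immigrant. The default, together with
#'   `adult_survival` and `recruit_prob`, is calibrated so that about 50% of
#'   breeders are immigrants.
#' @param disp_median_male_m,disp_median_female_m median natal dispersal
#'   distance by sex, metres. Defaults 700 and 1050 (ratio 1.5, difference
#'   350 m, both medians under 1 km).
#' @param disp_sdlog log-scale spread of the log-normal dispersal kernel
#'   (or Weibull shape when `kernel_family = "weibull"` via
#'   `disp_weibull_shape`).
#' @param disp_weibull_shape shape parameter used when `kernel_family` is
#'   `"weibull"`.
#' @param kernel_family natal dispersal kernel family.
#' @param edge_behaviour what happens when a recruit's dispersal target falls
#'   outside the woodland: `"emigrate"` (the recruit leaves the monitored
#'   population and is lost, the realistic default for an open wood) or
#'   `"settle_nearest"` (settle at the nearest free box regardless).
#' @param n_autosomal_snps,n_z_snps marker counts on autosomes and on the Z.
#' @param n_autosomes number of autosomes the markers are spread over.
#' @param autosome_length_bp,z_length_bp physical chromosome lengths.
#' @param recomb_cm_per_mb recombination rate; crossovers per chromosome are
#'   Poisson with mean equal to the map length in Morgans.
#' @param founder_maf_beta two Beta parameters for founder allele frequencies
#'   (frequencies are redrawn until inside `[0.05, 0.95]`, emulating an
#'   ascertained SNP panel).
#' @param immigrant_divergence_fst realized pairwise F_ST between the
#'   external immigrant allele-frequency pool and the founder pool
#'   (Balding-Nichols perturbation, see [immigrant_pool_freqs()]). Zero makes
#'   immigrants genetically indistinguishable from founders.
#' @param epp_rate probability an offspring's genetic sire is not the social
#'   box mate but a nearby breeding male.
#' @param epp_radius_m radius within which extra-pair sires are drawn.
#' @param n_years number of simulated breeding seasons.
#' @param track_genotypes if `FALSE`, run demography and pedigree only (much
#'   faster; used for dispersal and immigration censuses).
#' @param max_genotyped cap on the number of breeders whose genotypes are
#'   archived (first-come at first breeding).
#' @param missing_rate genotype missingness injected into archived calls.
#' @param seed master RNG seed; the whole run is reproducible from it.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [sim_preset()], [run_simulation()], [build_landscape()]
#' @export
sim_config <- function(n_boxes = 1019,
                       extent_m = 4000,
                       occupancy = 0.30,
                       adult_survival = 0.50,
                       recruit_prob = 0.10,
                       clutch_size_mean = 6.8,
                       immigration_fill = 0.95,
                       disp_median_male_m = 700,
                       disp_median_female_m = 1050,
                       disp_sdlog = 0.45,
                       disp_weibull_shape = 1.4,
                       kernel_family = c("lognormal", "weibull"),
                       edge_behaviour = c("emigrate", "settle_nearest"),
                       n_autosomal_snps = 5000,
                       n_z_snps = 500,
                       n_autosomes = 10,
                       autosome_length_bp = 1e8,
                       z_length_bp = 7.5e7,
                       recomb_cm_per_mb = 2,
                       founder_maf_beta = c(1, 1),
                       immigrant_divergence_fst = 0.001,
                       epp_rate = 0.08,
                       epp_radius_m = 300,
                       n_years = 20,
                       track_genotypes = TRUE,
                       max_genotyped = 1000,
                       missing_rate = 0,
                       seed = 1L) {
  kernel_family <- match.arg(kernel_family)
  edge_behaviour <- match.arg(edge_behaviour)
  cfg <- list(
    n_boxes = as.integer(n_boxes), extent_m = extent_m, occupancy = occupancy,
    adult_survival = adult_survival, recruit_prob = recruit_prob,
    clutch_size_mean = clutch_size_mean, immigration_fill = immigration_fill,
    disp_median_male_m = disp_median_male_m,
    disp_median_female_m = disp_median_female_m,
    disp_sdlog = disp_sdlog, disp_weibull_shape = disp_weibull_shape,
    kernel_family = kernel_family, edge_behaviour = edge_behaviour,
    n_autosomal_snps = as.integer(n_autosomal_snps),
    n_z_snps = as.integer(n_z_snps),
    n_autosomes = as.integer(n_autosomes),
    autosome_length_bp = autosome_length_bp, z_length_bp = z_length_bp,
    recomb_cm_per_mb = recomb_cm_per_mb,
    founder_maf_beta = founder_maf_beta,
    immigrant_divergence_fst = immigrant_divergence_fst,
    epp_rate = epp_rate, epp_radius_m = epp_radius_m,
    n_years = as.integer(n_years),
    track_genotypes = isTRUE(track_genotypes),
    max_genotyped = max_genotyped, missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pr <- c("occupancy", "adult_survival", "recruit_prob", "immigration_fill",
          "epp_rate", "missing_rate")
  for (p in pr) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop_cfg("'%s' must be a probability in [0, 1]", p)
  }
  if (cfg$n_boxes < 2) stop_cfg("'n_boxes' must be at least 2")
  if (!is.finite(cfg$extent_m) || cfg$extent_m <= 0)
    stop_cfg("'extent_m' must be positive")
  if (cfg$disp_median_female_m < cfg$disp_median_male_m)
    stop_cfg("female dispersal median must be >= male dispersal median")
  if (cfg$immigrant_divergence_fst < 0 || cfg$immigrant_divergence_fst >= 0.5)
    stop_cfg("'immigrant_divergence_fst' must be in [0, 0.5)")
  if (cfg$clutch_size_mean <= 0) stop_cfg("'clutch_size_mean' must be positive")
  if (cfg$n_years < 1) stop_cfg("'n_years' must be at least 1")
  if (length(cfg$founder_maf_beta) != 2 || any(cfg$founder_maf_beta <= 0))
    stop_cfg("'founder_maf_beta' must be two positive Beta parameters")
  invisible(cfg)
}

#' Pre-defined simulation scales
#'
#' `"desk"` is the default working scale (~1019 boxes, 20 years, 5000
#' autosomal + 500 Z SNPs, genotype archive capped at 1000 breeders).
#' `"paper_like"` is the larger scale of a 10K-SNP-chip study (~2600
#' genotyped breeders, 10,000 markers, 25 years). `"neutral"` is a small
#' random-mating population with non-overlapping generations (adult survival
#' zero, no immigration, spatially unstructured settlement) used for neutral
#' drift expectations such as the Z-to-autosome diversity ratio.
#'
#' @param name preset name.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_preset <- function(name = c("desk", "paper_like", "neutral"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    desk = list(),
    paper_like = list(n_autosomal_snps = 9000L, n_z_snps = 1000L,
                      n_years = 25L, max_genotyped = 2600),
    neutral = list(n_boxes = 30L, occupancy = 0.4, adult_survival = 0,
                   recruit_prob = 0.9, immigration_fill = 0,
                   clutch_size_mean = 6.8,
                   disp_median_male_m = 1e6, disp_median_female_m = 1e6,
                   edge_behaviour = "settle_nearest",
                   recomb_cm_per_mb = 10,
                   epp_rate = 0, n_autosomal_snps = 1500L, n_z_snps = 1500L,
                   n_years = 40L, max_genotyped = Inf)
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(sim_config, base)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Nestbox population simulation configuration\n")
  cat(sprintf("  landscape : %d boxes, %.0f m extent, %.0f%% occupancy\n",
              x$n_boxes, x$extent_m, 100 * x$occupancy))
  cat(sprintf("  turnover  : adult survival %.2f, recruit prob %.3f, immigration fill %.2f\n",
              x$adult_survival, x$recruit_prob, x$immigration_fill))
  cat(sprintf("  dispersal : %s kernel, medians M %.0f m / F %.0f m\n",
              x$kernel_family, x$disp_median_male_m, x$disp_median_female_m))
  cat(sprintf("  genome    : %d autosomal SNPs on %d chromosomes + %d Z SNPs, EPP rate %.2f\n",
              x$n_autosomal_snps, x$n_autosomes, x$n_z_snps, x$epp_rate))
  cat(sprintf("  run       : %d years, seed %d, genotypes %s\n",
              x$n_years, x$seed,
              if (x$track_genotypes) "tracked" else "not tracked"))
  invisible(x)
}
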