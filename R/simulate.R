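# Forward-in-time simulator of a nestbox population with an annual cycle:
# adult survival, box retention, natal dispersal of local recruits with
# sex-specific kernels, vacancy filling by immigrants, monogamous pairing at
# boxes, Mendelian transmission with recombination on autosomes, and ZW
# transmission on the sex chromosome (sons: one Z from each parent; daughters:
# the single Z is a recombined paternal gamete).

# Fast per-chromosome gamete used inside the simulation loop. `idx` and
# `relpos` are precomputed per-chromosome locus indices / relative positions.
gamete_fast <- function(h1, h2, idx, relpos, morg) {
  out <- integer(length(h1))
  for (k in seq_along(idx)) {
    ii <- idx[[k]]
    nx <- stats::rpois(1L, morg[k])
    start <- sample.int(2L, 1L) - 1L
    if (nx == 0L) {
      out[ii] <- if (start == 0L) h1[ii] else h2[ii]
    } else {
      seg <- findInterval(relpos[[k]], sort(stats::runif(nx)))
      pick <- (start + seg) %% 2L
      o <- h1[ii]
      sw <- pick == 1L
      o[sw] <- h2[ii][sw]
      out[ii] <- o
    }
  }
  out
}

draw_kernel <- function(n, median_m, config) {
  if (config$kernel_family == "lognormal") {
    stats::rlnorm(n, meanlog = log(median_m), sdlog = config$disp_sdlog)
  } else {
    k <- config$disp_weibull_shape
    stats::rweibull(n, shape = k, scale = median_m / log(2)^(1 / k))
  }
}

#' Run the forward simulation
#'
#' Simulates `config$n_years` breeding seasons. Each year: (1) breeding pairs
#' form at boxes holding one male and one female; (2) each pair fledges a
#' Poisson clutch, of which a binomial share become local recruit candidates;
#' with probability `epp_rate` an offspring's genetic sire is a random male
#' breeding within `epp_radius_m` of the natal box while the social sire
#' remains the box mate; (3) adults survive to the next year with probability
#' `adult_survival` and retain their boxes; (4) recruit candidates settle, in
#' random order, at the nearest active box with a free slot for their sex
#' relative to a target point drawn from the sex-specific dispersal kernel
#' (distance from the kernel, direction uniform; ties broken toward the
#' lowest box id); (5) remaining vacancies are filled by immigrants drawn
#' from an external Balding-Nichols-differentiated allele-frequency pool with
#' probability `immigration_fill`. Genotypes of breeders are archived (up to
#' `max_genotyped`) at their first breeding.
#'
#' If the population runs out of breeding pairs the run stops and the result
#' is flagged extinct at that year rather than failing.
#'
#' @param config a [sim_config()].
#' @return an object of class `woodsim` with elements `pedigree`, `breeding`
#'   (year x box x pair table), `census` (per-year breeder counts and
#'   immigrant fraction), `dispersal` (realized natal dispersal of settled
#'   recruits), `map`, `loci`, genotype archive, allele-frequency pools, and
#'   extinction status.
#' @seealso [sim_genotypes()], [realized_immigrant_fraction()],
#'   [dispersal_medians()]
#' @export
run_simulation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  map <- build_landscape(config, use_seed = FALSE)
  bx <- map$x[order(map$box_id)]
  by <- map$y[order(map$box_id)]
  nb <- config$n_boxes
  # woodland boundary for dispersal: circle through the outermost box,
  # centred on the box centroid, with a small margin
  wood_cx <- mean(bx); wood_cy <- mean(by)
  wood_r2 <- max((bx - wood_cx)^2 + (by - wood_cy)^2) * 1.05^2

  loci <- make_locus_table(config)
  morg_named <- attr(loci, "morgans")
  La <- config$n_autosomal_snps
  Lz <- config$n_z_snps
  a_i <- seq_len(La)
  z_i <- La + seq_len(Lz)
  # per-chromosome locus indices and relative positions, autosomes then Z
  idxA <- split(seq_len(La), loci$chrom[a_i])
  idxA <- idxA[as.character(seq_len(config$n_autosomes))]
  relA <- lapply(idxA, function(ii) loci$pos_bp[ii] / config$autosome_length_bp)
  morgA <- unname(morg_named[names(idxA)])
  idxZ <- list(seq_len(Lz))
  relZ <- list(loci$pos_bp[z_i] / config$z_length_bp)
  morgZ <- unname(morg_named["Z"])
  track <- config$track_genotypes

  founder_p <- draw_founder_freqs(La + Lz, config$founder_maf_beta)
  imm_p <- immigrant_pool_freqs(founder_p, config$immigrant_divergence_fst)
  pa <- founder_p[a_i]; pz <- founder_p[z_i]
  ipa <- imm_p[a_i]; ipz <- imm_p[z_i]

  # --- individual registry -------------------------------------------------
  n_next <- 1L
  sex_v <- character(0); by_v <- integer(0); st_v <- character(0)
  nb_v <- integer(0)
  ped_rows <- list()
  new_inds <- function(n, sex, birth_year, natal_box, status,
                       dam = NA_integer_, sire = NA_integer_,
                       ssire = NA_integer_) {
    ids <- seq.int(n_next, length.out = n)
    n_next <<- n_next + n
    sex_v[ids] <<- sex; by_v[ids] <<- birth_year
    nb_v[ids] <<- natal_box; st_v[ids] <<- status
    ped_rows[[length(ped_rows) + 1L]] <<- data.frame(
      id = ids, sex = sex, birth_year = birth_year, natal_box = natal_box,
      status = status, dam = dam, sire = sire, social_sire = ssire)
    ids
  }

  # --- haplotype store for living individuals ------------------------------
  hap <- new.env(parent = emptyenv())
  hap$ids <- integer(0)
  if (track) {
    hap$A1 <- hap$A2 <- matrix(integer(0), 0, La)
    hap$Z1 <- hap$Z2 <- matrix(integer(0), 0, Lz)
  }
  hap_add <- function(ids, A1, A2, Z1, Z2) {
    hap$ids <- c(hap$ids, ids)
    hap$A1 <- rbind(hap$A1, A1); hap$A2 <- rbind(hap$A2, A2)
    hap$Z1 <- rbind(hap$Z1, Z1); hap$Z2 <- rbind(hap$Z2, Z2)
  }
  hap_prune <- function(keep_ids) {
    k <- hap$ids %in% keep_ids
    hap$ids <- hap$ids[k]
    hap$A1 <- hap$A1[k, , drop = FALSE]; hap$A2 <- hap$A2[k, , drop = FALSE]
    hap$Z1 <- hap$Z1[k, , drop = FALSE]; hap$Z2 <- hap$Z2[k, , drop = FALSE]
  }

  # --- genotype archive (breeders, first come) -----------------------------
  gt_ids <- integer(0); gt_rows <- list()
  archive <- function(ids) {
    if (!track) return(invisible())
    new <- setdiff(ids, gt_ids)
    room <- config$max_genotyped - length(gt_ids)
    if (room <= 0 || !length(new)) return(invisible())
    new <- new[seq_len(min(length(new), room))]
    r <- match(new, hap$ids)
    doseA <- hap$A1[r, , drop = FALSE] + hap$A2[r, , drop = FALSE]
    doseZ <- hap$Z1[r, , drop = FALSE]
    male <- sex_v[new] == "M"
    if (any(male))
      doseZ[male, ] <- doseZ[male, , drop = FALSE] +
        hap$Z2[r[male], , drop = FALSE]
    for (j in seq_along(new))
      gt_rows[[length(gt_rows) + 1L]] <<- c(doseA[j, ], doseZ[j, ])
    gt_ids <<- c(gt_ids, new)
  }

  # --- founders ------------------------------------------------------------
  B <- max(1L, round(config$occupancy * nb))
  active <- logical(nb)
  active[sample.int(nb, B)] <- TRUE
  m_ids <- new_inds(B, "M", 0L, NA_integer_, "local")
  f_ids <- new_inds(B, "F", 0L, NA_integer_, "local")
  if (track) {
    hap_add(m_ids, draw_haplotypes(B, pa), draw_haplotypes(B, pa),
            draw_haplotypes(B, pz), draw_haplotypes(B, pz))
    hap_add(f_ids, draw_haplotypes(B, pa), draw_haplotypes(B, pa),
            draw_haplotypes(B, pz), matrix(NA_integer_, B, Lz))
  }
  male_occ <- female_occ <- rep(NA_integer_, nb)
  male_occ[active] <- m_ids
  female_occ[active] <- f_ids

  breed_rows <- list(); census_rows <- list(); disp_rows <- list()
  extinct <- FALSE; extinct_year <- NA_integer_

  for (year in seq_len(config$n_years)) {
    pair_box <- which(active & !is.na(male_occ) & !is.na(female_occ))
    if (!length(pair_box)) { extinct <- TRUE; extinct_year <- year; break }
    pm <- male_occ[pair_box]; pf <- female_occ[pair_box]
    breed_rows[[year]] <- data.frame(year = year, box_id = pair_box,
                                     male_id = pm, female_id = pf)
    breeders <- c(pm, pf)
    census_rows[[year]] <- data.frame(
      year = year, n_pairs = length(pair_box), n_breeders = length(breeders),
      n_immigrant = sum(st_v[breeders] == "immigrant"),
      frac_immigrant = mean(st_v[breeders] == "immigrant"))
    archive(breeders)

    # --- reproduction: recruit candidates born this year -------------------
    clutch <- stats::rpois(length(pair_box), config$clutch_size_mean)
    nrec <- stats::rbinom(length(pair_box), clutch, config$recruit_prob)
    tot <- sum(nrec)
    cand_ids <- integer(0)
    if (tot > 0) {
      brood <- rep(seq_along(pair_box), nrec)
      c_sex <- sample(c("M", "F"), tot, replace = TRUE)
      c_box <- pair_box[brood]
      c_dam <- pf[brood]
      c_ssire <- pm[brood]
      c_sire <- c_ssire
      if (config$epp_rate > 0) {
        epp <- which(stats::runif(tot) < config$epp_rate)
        for (o in epp) {
          b <- c_box[o]
          d2 <- (bx[pair_box] - bx[b])^2 + (by[pair_box] - by[b])^2
          near <- pm[d2 <= config$epp_radius_m^2 & pm != c_ssire[o]]
          if (length(near)) c_sire[o] <- near[sample.int(length(near), 1L)]
        }
      }
      cand_ids <- new_inds(tot, c_sex, year, c_box, "local",
                           dam = c_dam, sire = c_sire, ssire = c_ssire)
      if (track) {
        A1 <- matrix(0L, tot, La); A2 <- matrix(0L, tot, La)
        Z1 <- matrix(NA_integer_, tot, Lz); Z2 <- matrix(NA_integer_, tot, Lz)
        for (o in seq_len(tot)) {
          rd <- match(c_dam[o], hap$ids); rs <- match(c_sire[o], hap$ids)
          A1[o, ] <- gamete_fast(hap$A1[rd, ], hap$A2[rd, ], idxA, relA, morgA)
          A2[o, ] <- gamete_fast(hap$A1[rs, ], hap$A2[rs, ], idxA, relA, morgA)
          Z1[o, ] <- gamete_fast(hap$Z1[rs, ], hap$Z2[rs, ], idxZ, relZ, morgZ)
          if (c_sex[o] == "M") Z2[o, ] <- hap$Z1[rd, ]  # maternal Z, unrecombined
        }
        hap_add(cand_ids, A1, A2, Z1, Z2)
      }
    }

    if (year == config$n_years) break

    # --- survival and box retention ----------------------------------------
    for (slot in c("m", "f")) {
      occ <- if (slot == "m") male_occ else female_occ
      has <- which(!is.na(occ))
      dead <- has[stats::runif(length(has)) >= config$adult_survival]
      occ[dead] <- NA_integer_
      if (slot == "m") male_occ <- occ else female_occ <- occ
    }
    occupied <- !is.na(male_occ) | !is.na(female_occ)
    active <- occupied
    short <- B - sum(active)
    if (short > 0) {
      pool <- which(!active)
      active[pool[sample.int(length(pool), min(short, length(pool)))]] <- TRUE
    }

    # --- settlement of local recruits --------------------------------------
    if (length(cand_ids)) {
      ord <- sample(seq_along(cand_ids))
      for (o in ord) {
        id <- cand_ids[o]
        free <- if (sex_v[id] == "M") {
          which(active & is.na(male_occ))
        } else {
          which(active & is.na(female_occ))
        }
        if (!length(free)) next
        nbx <- nb_v[id]
        dist <- draw_kernel(1L, if (sex_v[id] == "M") config$disp_median_male_m
                            else config$disp_median_female_m, config)
        ang <- stats::runif(1L, 0, 2 * pi)
        tx <- bx[nbx] + dist * cos(ang); ty <- by[nbx] + dist * sin(ang)
        # a target outside the woodland is an emigration event: the recruit
        # leaves the monitored population and is lost
        if (config$edge_behaviour == "emigrate" &&
            (tx - wood_cx)^2 + (ty - wood_cy)^2 > wood_r2) next
        j <- free[which.min((bx[free] - tx)^2 + (by[free] - ty)^2)]
        if (sex_v[id] == "M") male_occ[j] <- id else female_occ[j] <- id
        disp_rows[[length(disp_rows) + 1L]] <- data.frame(
          id = id, sex = sex_v[id], natal_box = nbx, settle_box = j,
          settle_year = year + 1L,
          distance_m = euclid(bx[nbx], by[nbx], bx[j], by[j]))
      }
    }

    # --- immigrant fill ----------------------------------------------------
    for (slot in c("m", "f")) {
      occ <- if (slot == "m") male_occ else female_occ
      free <- which(active & is.na(occ))
      fill <- free[stats::runif(length(free)) < config$immigration_fill]
      if (length(fill)) {
        ids <- new_inds(length(fill), if (slot == "m") "M" else "F",
                        NA_integer_, NA_integer_, "immigrant")
        if (track) {
          n <- length(ids)
          hap_add(ids, draw_haplotypes(n, ipa), draw_haplotypes(n, ipa),
                  draw_haplotypes(n, ipz),
                  if (slot == "m") draw_haplotypes(n, ipz)
                  else matrix(NA_integer_, n, Lz))
        }
        occ[fill] <- ids
      }
      if (slot == "m") male_occ <- occ else female_occ <- occ
    }

    if (track) {
      alive <- c(male_occ[!is.na(male_occ)], female_occ[!is.na(female_occ)])
      hap_prune(alive)
    }
  }

  pedigree <- do.call(rbind, ped_rows)
  rownames(pedigree) <- NULL
  dosage <- NULL
  if (track && length(gt_rows)) {
    dosage <- do.call(rbind, gt_rows)
    rownames(dosage) <- as.character(gt_ids)
    colnames(dosage) <- sprintf("snp%05d", seq_len(ncol(dosage)))
    if (config$missing_rate > 0)
      dosage[stats::runif(length(dosage)) < config$missing_rate] <- NA_integer_
  }
  loci$snp_id <- sprintf("snp%05d", seq_len(nrow(loci)))
  res <- list(
    config = config, map = map, loci = loci,
    pedigree = pedigree,
    breeding = do.call(rbind, breed_rows),
    census = do.call(rbind, census_rows),
    dispersal = if (length(disp_rows)) do.call(rbind, disp_rows) else
      data.frame(id = integer(0), sex = character(0), natal_box = integer(0),
                 settle_box = integer(0), settle_year = integer(0),
                 distance_m = numeric(0)),
    genotyped_ids = gt_ids, dosage = dosage,
    founder_freqs = founder_p, immigrant_freqs = imm_p,
    extinct = extinct, extinct_year = extinct_year
  )
  class(res) <- "woodsim"
  res
}

#' @export
print.woodsim <- function(x, ...) {
  cat("Simulated nestbox population\n")
  if (x$extinct) {
    cat(sprintf("  extinct at year %d\n", x$extinct_year))
  } else {
    cat(sprintf("  %d years, %d individuals in pedigree, %d genotyped breeders\n",
                max(x$census$year), nrow(x$pedigree), length(x$genotyped_ids)))
    cat(sprintf("  mean pairs/year %.1f, immigrant fraction of breeders %.2f\n",
                mean(x$census$n_pairs), mean(x$census$frac_immigrant)))
  }
  invisible(x)
}

#' Genotype matrix of the archived (genotyped) breeders
#'
#' @param sim a `woodsim`.
#' @return a [geno_matrix()] of allele dosages: autosomal calls in
#'   `{0, 1, 2}`, Z calls in `{0, 1, 2}` for males and single-copy `{0, 1}`
#'   for females.
#' @export
sim_genotypes <- function(sim) {
  if (is.null(sim$dosage)) stop_cfg("simulation was run without genotype tracking")
  ids <- sim$genotyped_ids
  ped <- sim$pedigree[match(ids, sim$pedigree$id), ]
  samples <- data.frame(id = as.character(ids), sex = ped$sex,
                        status = ped$status, birth_year = ped$birth_year,
                        natal_box = ped$natal_box, stringsAsFactors = FALSE)
  geno_matrix(sim$dosage, data.frame(snp_id = sim$loci$snp_id,
                                     chrom = sim$loci$chrom,
                                     pos_bp = sim$loci$pos_bp,
                                     stringsAsFactors = FALSE),
              samples)
}

#' Realized immigrant fraction among breeders
#'
#' @param sim a `woodsim`.
#' @param burnin years discarded before averaging.
#' @return mean per-year fraction of breeding adults flagged immigrant.
#' @export
realized_immigrant_fraction <- function(sim, burnin = 5) {
  cen <- sim$census[sim$census$year > burnin, ]
  if (!nrow(cen)) stop_cfg("no census years beyond the burn-in")
  mean(cen$frac_immigrant)
}

#' Median realized natal dispersal by sex
#'
#' Distances from natal box to first breeding box of settled local recruits.
#' @param sim a `woodsim`.
#' @return named list with `male`, `female` medians (m) and their ratio.
#' @export
dispersal_medians <- function(sim) {
  d <- sim$dispersal
  m <- stats::median(d$distance_m[d$sex == "M"])
  f <- stats::median(d$distance_m[d$sex == "F"])
  list(male = m, female = f, ratio = f / m)
}

#' Mean parent-offspring age gap (generation time)
#'
#' Computed over pedigree links whose parent has a known birth year
#' (immigrant parents, of unknown age, are excluded).
#' @param sim a `woodsim`.
#' @return generation time in years.
#' @export
generation_time <- function(sim) {
  ped <- sim$pedigree
  gaps <- c(ped$birth_year - ped$birth_year[match(ped$dam, ped$id)],
            ped$birth_year - ped$birth_year[match(ped$sire, ped$id)])
  mean(gaps[is.finite(gaps)])
}
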