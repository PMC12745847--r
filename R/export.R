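# Writers for the simulator's outputs: VCF 4.2 and PLINK text genotypes,
# pedigree and nestbox-location CSVs, and the configuration as JSON.
# Female Z calls are haploid in VCF ("0"/"1"); PLINK text has no haploid
# genotype, so the single allele is duplicated (standard hemizygous
# convention) and the affected loci are listed in a sidecar .zflag file that
# the reader uses to undo the duplication.

dose_to_gt <- function(dose, haploid) {
  gt <- character(length(dose))
  if (haploid) {
    gt[is.na(dose)] <- "."
    gt[!is.na(dose)] <- as.character(dose[!is.na(dose)])
  } else {
    gt[is.na(dose)] <- "./."
    gt[which(dose == 0)] <- "0/0"
    gt[which(dose == 1)] <- "0/1"
    gt[which(dose == 2)] <- "1/1"
  }
  gt
}

#' Write a genotype matrix as VCF 4.2
#'
#' Autosomal and male Z genotypes are diploid GT fields; female Z genotypes
#' are haploid GT fields.
#' @param g a [geno_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  n <- nrow(g$dosage); L <- ncol(g$dosage)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=woodgen",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$samples$id), collapse = "\t"))
  female <- g$samples$sex == "F" & !is.na(g$samples$sex)
  body <- vapply(seq_len(L), function(j) {
    hap <- g$loci$is_z[j] & female
    gt <- character(n)
    gt[hap] <- dose_to_gt(g$dosage[hap, j], TRUE)
    gt[!hap] <- dose_to_gt(g$dosage[!hap, j], FALSE)
    paste(c(g$loci$chrom[j], format(round(g$loci$pos_bp[j]), scientific = FALSE),
            g$loci$snp_id[j], "A", "G", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a genotype matrix as PLINK text (.ped/.map)
#'
#' @param g a [geno_matrix()].
#' @param basename output path without extension; writes `.ped`, `.map` and,
#'   when Z loci are present, a `.zflag` sidecar naming the loci whose female
#'   calls were duplicated to fake diploidy.
#' @return `basename`, invisibly.
#' @export
write_plink <- function(g, basename) {
  alleles <- c("A A", "A G", "G G")
  female <- g$samples$sex == "F" & !is.na(g$samples$sex)
  L <- ncol(g$dosage)
  gen <- matrix("0 0", nrow(g$dosage), L)
  for (j in seq_len(L)) {
    d <- g$dosage[, j]
    if (g$loci$is_z[j] && any(female)) {
      # duplicate the female single allele: 0 -> A A, 1 -> G G
      d[female] <- d[female] * 2L
    }
    ok <- !is.na(d)
    gen[ok, j] <- alleles[d[ok] + 1L]
  }
  sexcode <- ifelse(is.na(g$samples$sex), 0L,
                    ifelse(g$samples$sex == "M", 1L, 2L))
  ped <- cbind("FAM", g$samples$id, 0, 0, sexcode, -9, gen)
  utils::write.table(ped, paste0(basename, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  map <- data.frame(chrom = g$loci$chrom, snp = g$loci$snp_id, cm = 0,
                    pos = round(g$loci$pos_bp))
  utils::write.table(map, paste0(basename, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (any(g$loci$is_z))
    writeLines(g$loci$snp_id[g$loci$is_z], paste0(basename, ".zflag"))
  invisible(basename)
}

#' Export a completed simulation to files
#'
#' Writes `genotypes.vcf`, PLINK text (`genotypes.ped/.map/.zflag`),
#' `pedigree.csv`, `locations.csv`, a `samples.csv` sidecar with sample
#' metadata, and `config.json`.
#'
#' @param sim a `woodsim` run with genotype tracking.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
export_simulation <- function(sim, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop_cfg("cannot create output directory '%s'", outdir)
  g <- sim_genotypes(sim)
  write_vcf(g, file.path(outdir, "genotypes.vcf"))
  write_plink(g, file.path(outdir, "genotypes"))
  utils::write.csv(sim$pedigree, file.path(outdir, "pedigree.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$map), file.path(outdir, "locations.csv"),
                   row.names = FALSE)
  utils::write.csv(g$samples, file.path(outdir, "samples.csv"),
                   row.names = FALSE)
  cfg <- unclass(sim$config)
  jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
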