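#' Read genotypes from VCF or PLINK text
#'
#' VCF is parsed with \pkg{vcfR}; haploid GT fields (female Z) are honoured
#' as single-copy calls. PLINK `.ped`/`.map` text is parsed directly; if a
#' `.zflag` sidecar (written by [write_plink()]) lists Z loci, female calls at
#' those loci are converted back from the duplicated-allele convention to
#' single-copy dosages (a heterozygous female Z call is impossible under that
#' convention and becomes `NA` with a warning).
#'
#' @param path VCF file, or the `.ped` file / basename for PLINK text.
#' @param format `"vcf"` or `"plink_text"`.
#' @param samples optional sample metadata: a data frame or a CSV path with
#'   columns `id`, `sex`, `status`, ... joined to the genotypes by id.
#' @param z_chrom chromosome label(s) treated as Z.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text"),
                           samples = NULL, z_chrom = "Z") {
  format <- match.arg(format)
  g <- if (format == "vcf") read_vcf_geno(path, z_chrom)
       else read_plink_geno(path, z_chrom)
  if (!is.null(samples)) {
    meta <- if (is.character(samples)) {
      utils::read.csv(samples, stringsAsFactors = FALSE)
    } else samples
    meta$id <- as.character(meta$id)
    i <- match(g$samples$id, meta$id)
    for (cl in setdiff(names(meta), "id")) g$samples[[cl]] <- meta[[cl]][i]
  }
  warn_odd_chrom(g$loci$chrom)
  g
}

warn_odd_chrom <- function(chrom) {
  known <- grepl("^([0-9]+[A-Za-z]?|Z|W|LG.*|chr.*)$", unique(chrom))
  if (!all(known))
    warning(sprintf("unrecognised chromosome label(s) kept as-is: %s",
                    paste(unique(chrom)[!known], collapse = ", ")),
            call. = FALSE)
}

read_vcf_geno <- function(path, z_chrom) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  # gt: loci x samples character; count '1' alleles, NA for '.'
  n_alt <- function(s) {
    al <- strsplit(s, "[/|]")
    vapply(al, function(a) {
      if (length(a) == 0 || any(a == ".") || any(is.na(a))) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  }
  dose <- apply(gt, 2, n_alt)
  if (is.null(dim(dose))) dose <- matrix(dose, nrow = 1,
                                         dimnames = list(NULL, names(dose)))
  dose <- t(dose)
  loci <- data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                     pos_bp = as.numeric(fix[, "POS"]), stringsAsFactors = FALSE)
  # infer sex from Z ploidy: samples with any haploid Z call are female
  ploidy1 <- t(apply(gt, 2, function(s) !grepl("[/|]", s) & !is.na(s)))
  is_z <- loci$chrom %in% z_chrom
  sex <- rep(NA_character_, ncol(gt))
  if (any(is_z)) {
    hap_z <- rowSums(ploidy1[, is_z, drop = FALSE]) > 0
    dip_z <- rowSums(!ploidy1[, is_z, drop = FALSE] &
                       !is.na(t(gt[is_z, , drop = FALSE]))) > 0
    sex[hap_z] <- "F"; sex[!hap_z & dip_z] <- "M"
  }
  geno_matrix(dose, loci,
              data.frame(id = colnames(gt), sex = sex, stringsAsFactors = FALSE),
              z_chrom = z_chrom)
}

read_plink_geno <- function(path, z_chrom) {
  base <- sub("\\.ped$", "", path)
  ped_f <- paste0(base, ".ped"); map_f <- paste0(base, ".map")
  if (!file.exists(ped_f)) stop_cfg("PLINK .ped file not found: %s", ped_f)
  if (!file.exists(map_f)) stop_cfg("PLINK .map file not found: %s", map_f)
  map_lines <- readLines(map_f)
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_tok)
  if (any(nf != 4))
    stop_cfg("malformed .map record at line %d of %s",
             which(nf != 4)[1], map_f)
  map <- do.call(rbind, map_tok)
  loci <- data.frame(snp_id = map[, 2], chrom = map[, 1],
                     pos_bp = as.numeric(map[, 4]), stringsAsFactors = FALSE)
  L <- nrow(loci)
  ped_lines <- readLines(ped_f)
  tok <- strsplit(trimws(ped_lines), "[ \t]+")
  nf <- lengths(tok)
  if (any(nf != 6 + 2 * L))
    stop_cfg("malformed .ped record at line %d of %s (expected %d fields, got %d)",
             which(nf != 6 + 2 * L)[1], ped_f, 6 + 2 * L, nf[which(nf != 6 + 2 * L)[1]])
  ped <- do.call(rbind, tok)
  ids <- ped[, 2]
  sex <- c("1" = "M", "2" = "F")[ped[, 5]]
  a1 <- ped[, 6 + 2 * seq_len(L) - 1, drop = FALSE]
  a2 <- ped[, 6 + 2 * seq_len(L), drop = FALSE]
  dose <- (a1 == "G") + (a2 == "G")
  dose[a1 == "0" | a2 == "0"] <- NA
  # undo the duplicated-allele female-Z convention where flagged
  zflag_f <- paste0(base, ".zflag")
  if (file.exists(zflag_f)) {
    zsnps <- readLines(zflag_f)
    jz <- which(loci$snp_id %in% zsnps)
    fem <- which(sex == "F")
    if (length(jz) && length(fem)) {
      sub <- dose[fem, jz, drop = FALSE]
      if (any(sub == 1, na.rm = TRUE)) {
        warning("heterozygous female Z calls set to missing", call. = FALSE)
        sub[sub == 1] <- NA
      }
      dose[fem, jz] <- sub / 2
    }
  }
  geno_matrix(dose, loci,
              data.frame(id = ids, sex = unname(sex), stringsAsFactors = FALSE),
              z_chrom = z_chrom)
}
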