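# Relatedness-vs-distance machinery: binned decay curves with individual-level
# cluster bootstrap, simple slope summaries, penalized-spline fits per pair
# type, and the autosome-vs-Z by sex-pair contrast.

# Multiplicity-weighted cluster bootstrap over individuals: each replicate
# resamples individuals with replacement and keeps pairs whose both members
# were drawn, with multiplicity m_a * m_b.
pair_boot_weights <- function(ids_a, ids_b, n_boot) {
  ids <- unique(c(ids_a, ids_b))
  n <- length(ids)
  ia <- match(ids_a, ids); ib <- match(ids_b, ids)
  lapply(seq_len(n_boot), function(r) {
    cnt <- tabulate(sample.int(n, n, replace = TRUE), n)
    cnt[ia] * cnt[ib]
  })
}

#' Binned relatedness-decay curve
#'
#' Mean relatedness per distance bin with a cluster-bootstrap confidence
#' interval that resamples individuals (not pairs), respecting the
#' multi-membership structure of pairwise data. Bins without pairs are kept
#' as gaps (`NA` means).
#'
#' @param pairs annotated pair table.
#' @param value column holding the relatedness estimate.
#' @param dist column holding the distance in metres.
#' @param breaks bin edges in metres (default 500 m bins to 4 km).
#' @param n_boot bootstrap replicates (0 skips the CI).
#' @param conf confidence level.
#' @param stratum free-text label stored with the curve.
#' @return an object of class `decay_curve`: data frame `bin_lo`, `bin_hi`,
#'   `mid`, `mean`, `lo`, `hi`, `n_pairs`.
#' @export
decay_curve <- function(pairs, value = "pi_hat", dist = "breeding_distance_m",
                        breaks = seq(0, 4000, by = 500), n_boot = 200,
                        conf = 0.95, stratum = NA_character_) {
  v <- pairs[[value]]; d <- pairs[[dist]]
  ok <- !is.na(v) & !is.na(d) & d >= breaks[1] & d <= breaks[length(breaks)]
  v <- v[ok]; d <- d[ok]
  ids_a <- as.character(pairs$id_a[ok]); ids_b <- as.character(pairs$id_b[ok])
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  nb <- length(breaks) - 1
  n_pairs <- tabulate(bin, nb)
  mu <- rep(NA_real_, nb)
  sums <- rowsum(v, bin)
  mu[as.integer(rownames(sums))] <- sums / n_pairs[as.integer(rownames(sums))]
  lo <- hi <- rep(NA_real_, nb)
  if (n_boot > 0 && length(v)) {
    W <- pair_boot_weights(ids_a, ids_b, n_boot)
    reps <- vapply(W, function(w) {
      m <- rep(NA_real_, nb)
      wk <- w > 0
      if (!any(wk)) return(m)
      s1 <- rowsum(w[wk] * v[wk], bin[wk])
      s0 <- rowsum(w[wk], bin[wk])
      m[as.integer(rownames(s1))] <- s1 / s0
      m
    }, numeric(nb))
    reps <- matrix(reps, nrow = nb)
    a <- (1 - conf) / 2
    qs <- apply(reps, 1, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
    lo <- qs[1, ]; hi <- qs[2, ]
  }
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    mean = mu, lo = lo, hi = hi, n_pairs = n_pairs)
  attr(out, "stratum") <- stratum
  attr(out, "value") <- value
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("Relatedness decay curve%s\n",
              if (!is.na(attr(x, "stratum"))) paste0(" [", attr(x, "stratum"), "]")
              else ""))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
plot.decay_curve <- function(x, ...) {
  plot(x$mid, x$mean, type = "b", pch = 20, xlab = "distance (m)",
       ylab = attr(x, "value") %||% "relatedness", ...)
  if (!all(is.na(x$lo)))
    graphics::arrows(x$mid, x$lo, x$mid, x$hi, angle = 90, code = 3,
                     length = 0.03, col = "grey50")
  invisible(x)
}

#' Weighted linear slope of a decay curve
#'
#' Least-squares slope of bin means against bin midpoints, weighted by pair
#' counts; a quick scalar summary for curve comparisons.
#' @param curve a [decay_curve()].
#' @return slope per metre.
#' @export
curve_slope <- function(curve) {
  ok <- !is.na(curve$mean) & curve$n_pairs > 0
  if (sum(ok) < 2) return(NA_real_)
  stats::coef(stats::lm(mean ~ mid, data = curve[ok, ],
                        weights = curve$n_pairs[ok]))[["mid"]]
}

#' Pair-level linear relatedness-on-distance slope
#' @param pairs annotated pair table.
#' @param value,dist column names.
#' @return slope per metre.
#' @export
ibd_distance_slope <- function(pairs, value = "pi_hat",
                               dist = "breeding_distance_m") {
  ok <- !is.na(pairs[[value]]) & !is.na(pairs[[dist]])
  stats::coef(stats::lm(pairs[[value]][ok] ~ pairs[[dist]][ok]))[[2]]
}

#' Penalized-spline relatedness-on-distance fits by pair type
#'
#' Fits a penalized B-spline regression of relatedness on distance within
#' each stratum (by default the immigration pair type) and summarises each
#' smooth by `beta`, the average first derivative of the fitted curve over
#' the observed distance range. Uncertainty comes from a cluster bootstrap
#' over individuals (pairs enter each replicate with multiplicity
#' `m_a * m_b`, implemented as a weighted refit), which stands in for a
#' multi-membership random-effect structure.
#'
#' @param pairs annotated pair table.
#' @param strata column defining strata.
#' @param value,dist column names.
#' @param min_pairs strata with fewer pairs are skipped with a warning.
#' @param n_boot bootstrap replicates for the CI (0 = point estimates only).
#' @param conf confidence level.
#' @param k spline basis dimension.
#' @return object of class `ibd_fit`: a data frame with one row per stratum
#'   (`beta_per_km`, `beta_std` per SD of distance, CI bounds, `n_pairs`)
#'   and the fitted `mgcv::gam` objects in attribute `fits`.
#' @export
stratified_fit <- function(pairs, strata = "pair_type", value = "pi_hat",
                           dist = "breeding_distance_m", min_pairs = 200,
                           n_boot = 200, conf = 0.95, k = 10) {
  ok <- !is.na(pairs[[value]]) & !is.na(pairs[[dist]])
  pairs <- pairs[ok, , drop = FALSE]
  groups <- split(seq_len(nrow(pairs)), pairs[[strata]])
  rows <- list(); fits <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    if (length(idx) < min_pairs) {
      warning(sprintf("stratum '%s' has %d pairs (< %d), skipped",
                      gname, length(idx), min_pairs), call. = FALSE)
      next
    }
    df <- data.frame(v = pairs[[value]][idx],
                     d_km = pairs[[dist]][idx] / 1000,
                     id_a = as.character(pairs$id_a[idx]),
                     id_b = as.character(pairs$id_b[idx]))
    if (diff(range(df$d_km)) <= 0)
      stop_cfg("degenerate distance range in stratum '%s'", gname)
    kk <- min(k, max(4, length(unique(df$d_km)) - 1))
    fit <- mgcv::gam(v ~ s(d_km, bs = "ps", k = kk), data = df)
    beta <- mean_derivative(fit, df$d_km)
    lo <- hi <- NA_real_
    if (n_boot > 0) {
      W <- pair_boot_weights(df$id_a, df$id_b, n_boot)
      bs <- vapply(W, function(w) {
        if (sum(w > 0) < kk + 2 || diff(range(df$d_km[w > 0])) <= 0)
          return(NA_real_)
        f <- mgcv::gam(v ~ s(d_km, bs = "ps", k = kk), data = df, weights = w)
        mean_derivative(f, df$d_km[w > 0])
      }, numeric(1))
      a <- (1 - conf) / 2
      qs <- stats::quantile(bs, c(a, 1 - a), na.rm = TRUE)
      lo <- qs[[1]]; hi <- qs[[2]]
    }
    rows[[gname]] <- data.frame(
      stratum = gname, beta_per_km = beta,
      beta_std = beta * stats::sd(df$d_km),
      ci_lo = lo, ci_hi = hi, n_pairs = length(idx))
    fits[[gname]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("ibd_fit", "data.frame")
  out
}

# Average first derivative of the fitted smooth over the observed range,
# evaluated at the observed distances (so the average is weighted by where
# the data actually lie rather than by sparse range edges), by central
# finite differences.
mean_derivative <- function(fit, x) {
  h <- diff(range(x)) / 400
  p_up <- stats::predict(fit, newdata = data.frame(d_km = x + h))
  p_dn <- stats::predict(fit, newdata = data.frame(d_km = x - h))
  mean((p_up - p_dn) / (2 * h))
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat("Penalized-spline relatedness-on-distance fits\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Autosome versus Z decay curves by sex pair
#'
#' Builds the six decay curves (autosomes and Z, for MM/MF/FF pairs). The Z
#' pair table should carry male-male relatedness from diploid [mom_ibd()] and
#' copy-aware [z_relatedness()] values for pairs involving females (see
#' [z_pair_ibd()]).
#'
#' @param pairs_auto annotated autosomal pair table.
#' @param pairs_z annotated Z pair table.
#' @param value,dist,breaks,n_boot passed to [decay_curve()].
#' @return named list of six `decay_curve` objects
#'   (`auto_MM`, ..., `z_FF`), class `chrom_sex_contrast`.
#' @export
chrom_sex_contrast <- function(pairs_auto, pairs_z, value = "pi_hat",
                               dist = "breeding_distance_m",
                               breaks = seq(0, 4000, by = 500), n_boot = 0) {
  if (sum(!is.na(pairs_z[[value]])) < 10)
    warning("very few informative Z pairs", call. = FALSE)
  out <- list()
  for (sp in c("MM", "MF", "FF")) {
    out[[paste0("auto_", sp)]] <- decay_curve(
      pairs_auto[pairs_auto$sex_pair == sp, ], value, dist, breaks, n_boot,
      stratum = paste0("autosomes ", sp))
    out[[paste0("z_", sp)]] <- decay_curve(
      pairs_z[pairs_z$sex_pair == sp, ], value, dist, breaks, n_boot,
      stratum = paste0("Z ", sp))
  }
  class(out) <- "chrom_sex_contrast"
  out
}

#' Z-chromosome pairwise relatedness
#'
#' Male-male pairs always use the diploid method-of-moments estimator on the
#' Z. For pairs involving females two dialects exist in the wild and both are
#' provided. `"copy_aware"` uses the hemizygosity-aware moment estimator
#' ([z_relatedness()]), which treats the female Z as the single copy it is;
#' on this scale close cross-sex kin are highly related on the Z (a son
#' carries his mother's entire Z). `"plink_diploid"` instead reproduces the
#' convention of diploid SNP toolchains, where female Z calls are coded as
#' duplicated homozygous diploid genotypes and run through the ordinary
#' diploid estimator; under that convention relatedness involving females is
#' systematically attenuated on the Z, which is the behaviour underlying the
#' classic empirical observation that only male-male pairs show a clear Z
#' isolation-by-distance signal.
#'
#' @param gz a [geno_matrix()] restricted to Z loci.
#' @param maf_floor rare-variant exclusion for the method-of-moments runs.
#' @param dialect estimator for pairs involving females (see above).
#' @return pair table with `pi_hat` and `estimator`.
#' @export
z_pair_ibd <- function(gz, maf_floor = 0.1,
                       dialect = c("copy_aware", "plink_diploid")) {
  stopifnot(all(gz$loci$is_z))
  dialect <- match.arg(dialect)
  males <- gz$samples$sex == "M" & !is.na(gz$samples$sex)
  sex <- stats::setNames(gz$samples$sex, gz$samples$id)
  res <- list()
  if (sum(males) >= 2) {
    mm <- mom_ibd(subset_geno(gz, sample_idx = males), maf_floor = maf_floor)
    res$mm <- data.frame(id_a = mm$id_a, id_b = mm$id_b, pi_hat = mm$pi_hat,
                         estimator = "mom_diploid", stringsAsFactors = FALSE)
  }
  if (dialect == "copy_aware") {
    zr <- z_relatedness(gz)
    fem_pair <- sex[zr$id_a] == "F" | sex[zr$id_b] == "F"
    zr <- zr[fem_pair, , drop = FALSE]
    if (nrow(zr))
      res$f <- data.frame(id_a = zr$id_a, id_b = zr$id_b, pi_hat = zr$pi_hat,
                          estimator = "copy_aware", stringsAsFactors = FALSE)
  } else {
    gd <- gz
    fem <- which(gd$samples$sex == "F" & !is.na(gd$samples$sex))
    gd$dosage[fem, ] <- 2L * gd$dosage[fem, , drop = FALSE]
    gd$samples$sex <- "M"   # treat everyone as diploid, the toolchain way
    dp <- mom_ibd(gd, maf_floor = maf_floor)
    fem_pair <- sex[dp$id_a] == "F" | sex[dp$id_b] == "F"
    dp <- dp[fem_pair, , drop = FALSE]
    if (nrow(dp))
      res$f <- data.frame(id_a = dp$id_a, id_b = dp$id_b, pi_hat = dp$pi_hat,
                          estimator = "mom_plink_diploid",
                          stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
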