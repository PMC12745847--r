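# End-to-end replay: simulate a monitored woodland population, then run every
# analysis stage (QC, pruning, relatedness, spatial decay, temporal renewal,
# immigrant classification, F_ST scan) and bundle the results.

# Run one pipeline stage; on error, record the message in the collector
# environment and return NULL so later stages can still run.
stage_try <- function(failures, name, expr) {
  tryCatch(expr, error = function(e) {
    assign(name, conditionMessage(e), envir = failures)
    NULL
  })
}

#' Replay the full analysis pipeline on a simulated population
#'
#' Runs [run_simulation()] and the downstream stages in order, collecting a
#' report that mirrors the structure of a spatial population-genetics study:
#' spatial structure and isolation by distance (with kin stripping and
#' autosome/Z, sex-pair contrasts), temporal renewal within the two most
#' distant areas, immigrant classification, genome-wide differentiation, and
#' runs of homozygosity. Stage failures are recorded in `$failures` and do
#' not abort the rest of the pipeline. With `immigration_fill = 0` (closed
#' population) the immigrant analyses are skipped with a notice.
#'
#' @param config a [sim_config()].
#' @param qc,prune,classifier stage parameter objects.
#' @param n_boot bootstrap replicates used by curve/fit stages.
#' @param areas_k boxes per area for the renewal analysis.
#' @param breaks distance bin edges (m).
#' @param verbose print stage progress.
#' @return an object of class `replay_report`.
#' @export
replay <- function(config = sim_preset("desk"), qc = qc_params(),
                   prune = ld_prune_params(),
                   classifier = classifier_config(n_repeats = 20),
                   n_boot = 100, areas_k = 50,
                   breaks = seq(0, 4000, by = 500), verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  failures <- new.env(parent = emptyenv())
  notices <- character(0)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }

  say("simulating population ...")
  sim <- run_simulation(config)
  tick("simulate")
  if (sim$extinct) {
    return(structure(list(
      extinct = TRUE, extinct_year = sim$extinct_year, config = config,
      failures = list(simulate = sprintf("extinct at year %d", sim$extinct_year)),
      timings = timings), class = "replay_report"))
  }
  if (!config$track_genotypes)
    stop_cfg("replay needs a genotype-tracking configuration")

  g <- sim_genotypes(sim)
  samples <- g$samples
  closed <- all(samples$status == "local")
  if (closed)
    notices <- c(notices,
                 "closed population (no immigrants): immigrant analyses skipped")

  say("quality control ...")
  qcr <- apply_qc(g, qc)
  sp <- split_datasets(qcr$genotypes)
  g_auto <- sp$autosomal
  g_z <- sp$z_only
  pruned <- apply_ld_prune(g_auto, prune)
  tick("qc")

  say("PCA ...")
  pca <- stage_try(failures, "pca", geno_pca(pruned, n_pc = 15))
  tick("pca")

  say("relatedness ...")
  ibd <- mom_ibd(g_auto)
  king <- king_robust(g_auto)
  ibd$phi <- king$phi
  ibd$degree <- king$degree
  pairs <- pair_table(ibd, samples, breeding_records(sim), sim$map)
  tick("relatedness")

  say("isolation by distance ...")
  curves <- list(
    all = decay_curve(pairs, breaks = breaks, n_boot = n_boot, stratum = "all"),
    no_first = decay_curve(strip_kin(pairs, "no_first"), breaks = breaks,
                           n_boot = n_boot, stratum = "no_first"),
    no_first_second = decay_curve(strip_kin(pairs, "no_first_second"),
                                  breaks = breaks, n_boot = n_boot,
                                  stratum = "no_first_second"),
    distant_only = decay_curve(strip_kin(pairs, "distant_only"),
                               breaks = breaks, n_boot = n_boot,
                               stratum = "distant_only"))
  fits <- if (closed) NULL else
    stage_try(failures, "stratified_fit",
              stratified_fit(pairs, min_pairs = 50, n_boot = n_boot))
  zcontrast <- stage_try(failures, "z_contrast", {
    zp <- z_pair_ibd(g_z)
    zp <- pair_table(zp, samples, breeding_records(sim), sim$map)
    chrom_sex_contrast(pairs, zp, breaks = breaks)
  })
  tick("spatial")

  say("temporal renewal ...")
  renewal <- stage_try(failures, "renewal", {
    sel <- select_areas(sim$map, k = areas_k)
    list(selection = sel,
         lags = lag_curve(pairs, sel, samples, n_boot = n_boot))
  })
  tick("renewal")

  say("runs of homozygosity ...")
  roh <- stage_try(failures, "roh", {
    g_raw_auto <- subset_geno(g, loci_idx = !g$loci$is_z)
    segs <- detect_roh(g_raw_auto, roh_params())
    smry <- roh_summary(segs, sample_ids = samples$id)
    smry$status <- samples$status[match(smry$sample_id, samples$id)]
    list(segments = segs, summary = smry,
         by_status = stats::aggregate(
           cbind(n_roh, mean_length_kb, total_kb) ~ status, data = smry, FUN = mean))
  })
  tick("roh")

  classify <- nullrep <- divscan <- NULL
  if (!closed) {
    say("immigrant classification ...")
    classify <- stage_try(failures, "classifier",
                          classify_immigrants(pruned, classifier))
    if (!is.null(classify) && !is.null(classify$pca))
      nullrep <- stage_try(failures, "null_baseline",
                           null_baseline(classify$pca$scores,
                                         as.character(classify$labels),
                                         classifier))
    tick("classifier")

    say("F_ST scan ...")
    divscan <- stage_try(failures, "divscan", {
      per_snp <- fst_per_snp(g_auto, samples$status)
      win <- window_fst(per_snp)
      res <- list(global = global_fst(per_snp), windows = win)
      if (!is.null(classify) && !is.null(classify$mds)) {
        k_sub <- min(50, sum(classify$labels == "immigrant"),
                     sum(classify$labels == "local"))
        subs <- extreme_subsets(classify, k = k_sub, kinship = king)
        both <- c(subs$top_immigrants, subs$top_locals)
        g_sub <- subset_geno(g_auto, sample_idx = g_auto$samples$id %in% both)
        res$subsets <- subs
        res$subset_k <- k_sub
        res$global_subsets <- global_fst(
          fst_per_snp(g_sub, g_sub$samples$status))
      }
      res
    })
    tick("divscan")
  }

  structure(list(
    extinct = FALSE, config = config, qc_report = qcr$report,
    n_genotyped = nrow(samples),
    census = sim$census, dispersal_medians = dispersal_medians(sim),
    generation_time = generation_time(sim),
    immigrant_fraction = realized_immigrant_fraction(
      sim, burnin = min(5, config$n_years - 1)),
    pca = pca, pairs = pairs, curves = curves, fits = fits,
    z_contrast = zcontrast, renewal = renewal, roh = roh,
    classifier = classify, null_baseline = nullrep, divscan = divscan,
    notices = notices,
    failures = { fl <- as.list(failures); fl[sort(names(fl))] },
    timings = timings
  ), class = "replay_report")
}

#' @export
print.replay_report <- function(x, ...) {
  cat("Pipeline replay report\n")
  if (x$extinct) {
    cat(sprintf("  population extinct at year %d\n", x$extinct_year))
    return(invisible(x))
  }
  cat(sprintf("  genotyped breeders: %d; immigrant fraction %.2f; generation time %.2f y\n",
              x$n_genotyped, x$immigrant_fraction, x$generation_time))
  if (!is.null(x$fits)) {
    cat("  relatedness-on-distance beta (per km):\n")
    for (i in seq_len(nrow(x$fits)))
      cat(sprintf("    %-20s %+.4f\n", x$fits$stratum[i], x$fits$beta_per_km[i]))
  }
  if (!is.null(x$classifier))
    cat(sprintf("  classifier accuracy %.1f%%, null balanced %.1f%%\n",
                100 * x$classifier$accuracy_mean,
                if (!is.null(x$null_baseline)) 100 * x$null_baseline$mean else NA))
  if (!is.null(x$divscan))
    cat(sprintf("  global F_ST (immigrant vs local) %.2e\n", x$divscan$global))
  for (n in x$notices) cat("  note:", n, "\n")
  for (n in names(x$failures)) cat("  FAILED:", n, "-", x$failures[[n]], "\n")
  invisible(x)
}

# Strip a report down to deterministic plain values for JSON output.
report_summary <- function(x) {
  num <- function(v) if (is.null(v)) NULL else round(unname(v), 8)
  out <- list(
    extinct = x$extinct,
    seed = x$config$seed,
    n_genotyped = x$n_genotyped,
    immigrant_fraction = num(x$immigrant_fraction),
    generation_time = num(x$generation_time),
    dispersal_median_male_m = num(x$dispersal_medians$male),
    dispersal_median_female_m = num(x$dispersal_medians$female),
    dispersal_ratio = num(x$dispersal_medians$ratio),
    qc = list(n_loci_in = x$qc_report$n_loci_in, n_kept = x$qc_report$n_kept),
    pca_varexp = num(utils::head(x$pca$varexp, 5)),
    curve_slopes = lapply(x$curves, function(cv) num(curve_slope(cv))),
    notices = x$notices,
    failures = x$failures
  )
  if (!is.null(x$fits))
    out$beta_per_km <- stats::setNames(as.list(num(x$fits$beta_per_km)),
                                       x$fits$stratum)
  if (!is.null(x$renewal)) {
    out$renewal <- list(
      baseline = num(x$renewal$lags$baseline),
      crossing_lag = as.list(x$renewal$lags$crossing_lag),
      density_boxes_per_ha = num(x$renewal$selection$density_boxes_per_ha))
  }
  if (!is.null(x$classifier)) {
    out$classifier <- list(
      accuracy_mean = num(x$classifier$accuracy_mean),
      accuracy_sd = num(x$classifier$accuracy_sd),
      rate_local = num(x$classifier$rate_local),
      rate_immigrant = num(x$classifier$rate_immigrant),
      balanced_accuracy_mean = num(x$classifier$balanced_accuracy_mean),
      oob_error = num(x$classifier$oob_error))
    if (!is.null(x$null_baseline))
      out$classifier$null_balanced_accuracy_mean <- num(x$null_baseline$mean)
  }
  if (!is.null(x$divscan)) {
    out$fst <- list(global = num(x$divscan$global),
                    global_subsets = num(x$divscan$global_subsets),
                    n_windows = nrow(x$divscan$windows))
  }
  if (!is.null(x$roh))
    out$roh_by_status <- x$roh$by_status
  out
}

#' Write a replay report to disk
#'
#' Writes a deterministic `report.json` (summary quantities only), CSVs of
#' the main tables (decay curves, spline fits, lag curves, F_ST windows,
#' census, ROH summaries), and a `manifest.json` with seed, config hash,
#' stage timings and output digests. For a fixed seed and configuration,
#' `report.json` and the CSVs are byte-identical across runs.
#'
#' @param report a `replay_report`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop_cfg("cannot create output directory '%s'", outdir)
  jsonlite::write_json(report_summary(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  wcsv <- function(df, name) {
    if (!is.null(df))
      utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  if (!report$extinct) {
    wcsv(report$census, "census.csv")
    for (nm in names(report$curves))
      wcsv(as.data.frame(report$curves[[nm]]), paste0("curve_", nm, ".csv"))
    wcsv(as.data.frame(report$fits), "spline_fits.csv")
    if (!is.null(report$renewal)) {
      wcsv(report$renewal$lags$area_a, "lag_area_a.csv")
      wcsv(report$renewal$lags$area_b, "lag_area_b.csv")
    }
    if (!is.null(report$divscan)) wcsv(report$divscan$windows, "fst_windows.csv")
    if (!is.null(report$roh)) wcsv(report$roh$summary, "roh_summary.csv")
  }
  cfg_file <- tempfile()
  saveRDS(unclass(report$config), cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("woodgen")),
    seed = report$config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    timings_s = as.list(report$timings),
    outputs = as.list(tools::md5sum(
      list.files(outdir, pattern = "\\.(json|csv)$", full.names = TRUE) |>
        setdiff(file.path(outdir, "manifest.json"))))
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
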