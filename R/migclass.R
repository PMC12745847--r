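# Immigrant-vs-local classification: balanced stratified splits, a
# random-forest ensemble with averaged proximity and MDS embedding, and a
# randomized-label null baseline.

#' Classifier configuration
#'
#' @param train_frac training fraction of the balanced sample.
#' @param n_pcs number of principal components used as features.
#' @param n_forests forests in the proximity-averaging ensemble.
#' @param trees_per_forest trees per forest.
#' @param n_repeats train/test repetitions for the accuracy distribution.
#' @param null_forests forests per randomized-label repeat.
#' @param seed RNG seed for sampling and forests.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(train_frac = 0.70, n_pcs = 15, n_forests = 50,
                              trees_per_forest = 500, n_repeats = 50,
                              null_forests = 1, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop_cfg("'train_frac' must be in (0,1)")
  if (n_pcs < 2) stop_cfg("'n_pcs' must be at least 2")
  structure(list(train_frac = train_frac, n_pcs = as.integer(n_pcs),
                 n_forests = as.integer(n_forests),
                 trees_per_forest = as.integer(trees_per_forest),
                 n_repeats = as.integer(n_repeats),
                 null_forests = as.integer(null_forests),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Balanced stratified train/test split
#'
#' The majority class is undersampled to the minority size; the balanced set
#' is split `train_frac`/(1 - `train_frac`) stratified by class, so train and
#' test each hold equal class counts.
#'
#' @param status class labels (character/factor), one per sample.
#' @param cfg a [classifier_config()] (only `train_frac` is used).
#' @return list with integer index vectors `train` and `test` into `status`.
#' @export
balanced_split <- function(status, cfg = classifier_config()) {
  status <- as.character(status)
  cls <- sort(unique(status))
  if (length(cls) != 2) stop_cfg("need exactly two classes, got %d", length(cls))
  idx <- split(seq_along(status), status)
  n_min <- min(lengths(idx))
  if (n_min < 10) stop_cfg("smallest class has %d samples (< 10)", n_min)
  n_train <- floor(cfg$train_frac * n_min)
  train <- test <- integer(0)
  for (cl in cls) {
    pick <- sample(idx[[cl]], n_min)
    train <- c(train, pick[seq_len(n_train)])
    test <- c(test, pick[(n_train + 1):n_min])
  }
  list(train = sort(train), test = sort(test))
}

predict_class <- function(rf, x, levels) {
  pr <- stats::predict(rf, x, type = "prob")
  # ties resolved toward the first level ("local" when present)
  factor(levels[max.col(pr[, levels, drop = FALSE], ties.method = "first")],
         levels = levels)
}

rate_by_class <- function(truth, pred) {
  vapply(levels(truth), function(cl) {
    s <- truth == cl
    if (!any(s)) return(NA_real_)
    mean(pred[s] == cl)
  }, numeric(1))
}

#' Random-forest ensemble classifier
#'
#' Repeats `n_repeats` balanced splits, training one forest per repeat and
#' recording test accuracy and per-class rates. Separately, an ensemble of
#' `n_forests` forests is grown on a single balanced split; their proximity
#' matrices over the whole balanced sample are averaged, per-individual vote
#' fractions are accumulated, and the averaged proximity is embedded in two
#' dimensions by classical MDS of `1 - proximity`.
#'
#' @param features numeric feature matrix (rows = samples); the first
#'   `cfg$n_pcs` columns are used.
#' @param labels two-class labels, one per row of `features`. The level
#'   `"local"`, when present, is the tie-breaking class.
#' @param cfg a [classifier_config()].
#' @return object of class `classifier_report`.
#' @export
rf_ensemble <- function(features, labels, cfg = classifier_config()) {
  features <- as.matrix(features)
  if (anyNA(features) || any(!is.finite(features)))
    stop_cfg("features must be finite")
  labels <- as.character(labels)
  lv <- if (all(sort(unique(labels)) == c("immigrant", "local")))
    c("local", "immigrant") else sort(unique(labels))
  y <- factor(labels, levels = lv)
  X <- features[, seq_len(min(cfg$n_pcs, ncol(features))), drop = FALSE]
  set.seed(cfg$seed)

  acc <- bal <- numeric(cfg$n_repeats)
  rates <- matrix(NA_real_, cfg$n_repeats, 2, dimnames = list(NULL, lv))
  for (r in seq_len(cfg$n_repeats)) {
    sp <- balanced_split(y, cfg)
    rf <- randomForest::randomForest(X[sp$train, , drop = FALSE], y[sp$train],
                                     ntree = cfg$trees_per_forest)
    pred <- predict_class(rf, X[sp$test, , drop = FALSE], lv)
    acc[r] <- mean(pred == y[sp$test])
    rr <- rate_by_class(y[sp$test], pred)
    rates[r, ] <- rr
    bal[r] <- mean(rr)
  }

  # proximity-averaging ensemble on one balanced split
  sp <- balanced_split(y, cfg)
  bal_idx <- sort(c(sp$train, sp$test))
  Xb <- X[bal_idx, , drop = FALSE]
  tr <- match(sp$train, bal_idx)
  prox <- matrix(0, length(bal_idx), length(bal_idx))
  votes <- matrix(0, length(bal_idx), 2, dimnames = list(NULL, lv))
  oob <- numeric(cfg$n_forests)
  for (f in seq_len(cfg$n_forests)) {
    rf <- randomForest::randomForest(Xb[tr, , drop = FALSE], y[bal_idx][tr],
                                     ntree = cfg$trees_per_forest)
    # with proximity = TRUE, predict() returns list(predicted, proximity)
    pp <- stats::predict(rf, Xb, proximity = TRUE, type = "prob")
    prox <- prox + pp$proximity
    votes <- votes + pp$predicted[, lv]
    oob[f] <- rf$err.rate[cfg$trees_per_forest, "OOB"]
  }
  prox <- prox / cfg$n_forests
  votes <- votes / cfg$n_forests
  mds <- stats::cmdscale(stats::as.dist(1 - prox), k = 2)
  mds <- scale(mds, center = TRUE, scale = FALSE)
  colnames(mds) <- c("MDS1", "MDS2")

  structure(list(
    accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
    rate_local = mean(rates[, lv[1]]), rate_local_sd = stats::sd(rates[, lv[1]]),
    rate_immigrant = mean(rates[, lv[2]]),
    rate_immigrant_sd = stats::sd(rates[, lv[2]]),
    balanced_accuracy_mean = mean(bal), balanced_accuracy_sd = stats::sd(bal),
    oob_error = mean(oob),
    proximity = prox, mds = mds, vote_fraction = votes,
    sample_index = bal_idx, labels = y[bal_idx], levels = lv,
    config = cfg
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Random-forest immigrant/local classifier\n")
  cat(sprintf("  accuracy %.1f%% (sd %.1f), balanced %.1f%% (sd %.1f)\n",
              100 * x$accuracy_mean, 100 * x$accuracy_sd,
              100 * x$balanced_accuracy_mean, 100 * x$balanced_accuracy_sd))
  cat(sprintf("  per-class: %s %.1f%%, %s %.1f%%; OOB error %.1f%%\n",
              x$levels[1], 100 * x$rate_local, x$levels[2],
              100 * x$rate_immigrant, 100 * x$oob_error))
  invisible(x)
}

#' Randomized-label null baseline
#'
#' Permutes the class labels in each repeat and runs the same balanced-split
#' + forest pipeline, giving the distribution of balanced accuracy expected
#' with no real signal (centred on 50%).
#'
#' @param features,labels,cfg as in [rf_ensemble()].
#' @return list with `balanced_accuracy` (per repeat), `mean`, `sd`.
#' @export
null_baseline <- function(features, labels, cfg = classifier_config()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  lv <- if (all(sort(unique(labels)) == c("immigrant", "local")))
    c("local", "immigrant") else sort(unique(labels))
  X <- features[, seq_len(min(cfg$n_pcs, ncol(features))), drop = FALSE]
  set.seed(cfg$seed)
  bal <- numeric(cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    y <- factor(sample(labels), levels = lv)
    sp <- balanced_split(y, cfg)
    preds <- matrix(0, length(sp$test), 2, dimnames = list(NULL, lv))
    for (f in seq_len(cfg$null_forests)) {
      rf <- randomForest::randomForest(X[sp$train, , drop = FALSE], y[sp$train],
                                       ntree = cfg$trees_per_forest)
      preds <- preds + stats::predict(rf, X[sp$test, , drop = FALSE],
                                      type = "prob")[, lv]
    }
    pred <- factor(lv[max.col(preds, ties.method = "first")], levels = lv)
    bal[r] <- mean(rate_by_class(y[sp$test], pred))
  }
  list(balanced_accuracy = bal, mean = mean(bal), sd = stats::sd(bal))
}

#' Genotype-level immigrant classification
#'
#' Convenience wrapper: undersamples to a balanced set, fits the genotype PCA
#' (by default on the full balanced sample before splitting, mirroring common
#' practice; `leakage_safe = TRUE` instead fits the PCA on each training set
#' and projects the test set), then runs [rf_ensemble()].
#'
#' @param g a QC'd, LD-pruned autosomal [geno_matrix()] whose samples carry a
#'   two-level `status`.
#' @param cfg a [classifier_config()].
#' @param leakage_safe fit the PCA inside the training set of each repeat.
#' @return a `classifier_report` (with `pca` attached).
#' @export
classify_immigrants <- function(g, cfg = classifier_config(),
                                leakage_safe = FALSE) {
  status <- g$samples$status
  if (any(is.na(status))) stop_cfg("all samples need a status label")
  set.seed(cfg$seed)
  idx <- split(seq_along(status), status)
  n_min <- min(lengths(idx))
  bal_idx <- sort(unlist(lapply(idx, sample, size = n_min)))
  gb <- subset_geno(g, sample_idx = bal_idx)
  if (!leakage_safe) {
    message("PCA fitted on the full balanced sample before splitting; ",
            "set leakage_safe = TRUE to fit it per training set")
    pc <- geno_pca(gb, n_pc = cfg$n_pcs)
    rep <- rf_ensemble(pc$scores, gb$samples$status, cfg)
    rep$pca <- pc
    rep$sample_ids <- gb$samples$id[rep$sample_index]
    return(rep)
  }
  # leakage-safe: per-repeat PCA on the training set, test set projected
  lv <- c("local", "immigrant")
  y <- factor(gb$samples$status, levels = lv)
  bal <- acc <- numeric(cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    sp <- balanced_split(y, cfg)
    gtr <- subset_geno(gb, sample_idx = sp$train)
    p <- allele_freq(gtr)
    keep <- is.finite(p) & p > 0 & p < 1
    gtr <- subset_geno(gtr, loci_idx = keep)
    p <- p[keep]
    std <- function(d) {
      X <- sweep(d, 2, 2 * p, "-")
      X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
      X[is.na(X)] <- 0
      X
    }
    Xtr <- std(gtr$dosage)
    sv <- svd(Xtr, nu = 0, nv = cfg$n_pcs)
    Ftr <- Xtr %*% sv$v
    Fte <- std(gb$dosage[sp$test, keep, drop = FALSE]) %*% sv$v
    rf <- randomForest::randomForest(Ftr, y[sp$train],
                                     ntree = cfg$trees_per_forest)
    pred <- predict_class(rf, Fte, lv)
    acc[r] <- mean(pred == y[sp$test])
    bal[r] <- mean(rate_by_class(y[sp$test], pred))
  }
  structure(list(accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
                 balanced_accuracy_mean = mean(bal),
                 balanced_accuracy_sd = stats::sd(bal),
                 leakage_safe = TRUE, config = cfg),
            class = "classifier_report")
}
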