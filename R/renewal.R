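# Temporal renewal of spatial genetic structure: two maximally separated
# areas of the woodland, relatedness between birth cohorts at increasing time
# lags, and the cross-wood baseline they decay towards.

#' Select the two most distant areas of the woodland
#'
#' Anchors are the pair of boxes at maximal distance (ties broken toward the
#' lexicographically smallest box-id pair); each area is the `k` nearest
#' boxes around its anchor (anchor included). Overlapping member sets mean
#' the woodland is too small for the analysis and raise an error.
#'
#' @param map a [nestbox_map()].
#' @param k boxes per area.
#' @return object of class `area_selection`: anchors, member box ids, convex
#'   hull area (ha) and box density (boxes/ha) per area.
#' @export
select_areas <- function(map, k = 50) {
  boxes <- as.data.frame(map)
  n <- nrow(boxes)
  if (n < 2 * k + 2)
    stop_cfg("need at least 2k + 2 = %d boxes, have %d", 2 * k + 2, n)
  h <- if (n > 3) grDevices::chull(boxes$x, boxes$y) else seq_len(n)
  hb <- boxes[h, ]
  dm <- as.matrix(stats::dist(hb[, c("x", "y")]))
  mx <- max(dm)
  cand <- which(abs(dm - mx) < 1e-9, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  ids <- cbind(hb$box_id[cand[, 1]], hb$box_id[cand[, 2]])
  ids <- t(apply(ids, 1, sort))
  best <- order(ids[, 1], ids[, 2])[1]
  anchor_a <- ids[best, 1]; anchor_b <- ids[best, 2]
  near_k <- function(anchor) {
    ax <- boxes$x[boxes$box_id == anchor]; ay <- boxes$y[boxes$box_id == anchor]
    d <- euclid(boxes$x, boxes$y, ax, ay)
    boxes$box_id[order(d, boxes$box_id)][seq_len(k)]
  }
  mem_a <- near_k(anchor_a); mem_b <- near_k(anchor_b)
  if (length(intersect(mem_a, mem_b)))
    stop_cfg("area member sets overlap: the woodland is too small for k = %d", k)
  try_hull <- function(b) tryCatch(hull_density(b), error = function(e) {
    warning("degenerate area geometry: ", conditionMessage(e), call. = FALSE)
    list(area_ha = NA_real_, density = NA_real_)
  })
  hd_a <- try_hull(boxes[boxes$box_id %in% mem_a, ])
  hd_b <- try_hull(boxes[boxes$box_id %in% mem_b, ])
  structure(list(anchor_box_a = anchor_a, anchor_box_b = anchor_b,
                 member_boxes_a = mem_a, member_boxes_b = mem_b,
                 hull_area_ha = c(a = hd_a$area_ha, b = hd_b$area_ha),
                 density_boxes_per_ha = c(a = hd_a$density, b = hd_b$density)),
            class = "area_selection")
}

#' @export
print.area_selection <- function(x, ...) {
  cat(sprintf("Two most distant areas: anchors %s / %s, %d boxes each\n",
              x$anchor_box_a, x$anchor_box_b, length(x$member_boxes_a)))
  cat(sprintf("  hull areas %.1f / %.1f ha, densities %.1f / %.1f boxes/ha\n",
              x$hull_area_ha["a"], x$hull_area_ha["b"],
              x$density_boxes_per_ha["a"], x$density_boxes_per_ha["b"]))
  invisible(x)
}

#' Convex-hull area and box density
#'
#' Hull area by the shoelace formula on the convex hull of the boxes;
#' density is boxes per hectare of hull area.
#'
#' @param boxes data frame with `x`, `y` in metres.
#' @return list with `area_ha` and `density` (boxes/ha).
#' @export
hull_density <- function(boxes) {
  boxes <- as.data.frame(boxes)
  if (nrow(boxes) < 3) stop_cfg("need at least 3 boxes for a hull")
  h <- grDevices::chull(boxes$x, boxes$y)
  if (length(h) < 3) stop_cfg("boxes are collinear: hull area undefined")
  x <- boxes$x[h]; y <- boxes$y[h]
  area_m2 <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area_m2 <= 0) stop_cfg("boxes are collinear: hull area undefined")
  list(area_ha = area_m2 / 1e4, density = nrow(boxes) / (area_m2 / 1e4))
}

#' Relatedness across birth-cohort lags within the two most distant areas
#'
#' Birds belong to an area when their natal box is among its members (the
#' analysis concerns birth cohorts, so natal rather than breeding location
#' defines membership; immigrants, having no natal box, never qualify).
#' Within each area, pairs are grouped by absolute birth-year difference and
#' summarised by mean relatedness with a cluster-bootstrap CI. The baseline
#' is the mean relatedness of cross-area pairs born the same year, pooled
#' over years contributing at least `min_pairs` such pairs. The crossing lag
#' is the smallest lag whose CI contains the baseline.
#'
#' @param pairs pair table with a relatedness column.
#' @param sel an [select_areas()] result.
#' @param samples metadata with `id`, `natal_box`, `birth_year`.
#' @param value relatedness column.
#' @param max_lag largest lag tabulated (default: all observed).
#' @param n_boot,conf bootstrap settings.
#' @param min_pairs lags (and baseline years) with fewer pairs are flagged.
#' @return object of class `lag_curves`: per-area tables (`lag_years`,
#'   `mean`, `lo`, `hi`, `n_pairs`, `sparse`), the shared `baseline` (+ CI),
#'   and per-area `crossing_lag`.
#' @export
lag_curve <- function(pairs, sel, samples, value = "pi_hat", max_lag = NULL,
                      n_boot = 200, conf = 0.95, min_pairs = 10) {
  samples$id <- as.character(samples$id)
  area <- rep(NA_character_, nrow(samples))
  area[samples$natal_box %in% sel$member_boxes_a] <- "a"
  area[samples$natal_box %in% sel$member_boxes_b] <- "b"
  aa <- stats::setNames(area, samples$id)
  by <- stats::setNames(samples$birth_year, samples$id)
  a1 <- aa[as.character(pairs$id_a)]; a2 <- aa[as.character(pairs$id_b)]
  y1 <- by[as.character(pairs$id_a)]; y2 <- by[as.character(pairs$id_b)]
  v <- pairs[[value]]
  ok <- !is.na(v) & !is.na(a1) & !is.na(a2) & !is.na(y1) & !is.na(y2)

  # baseline: cross-area, same birth year, pooled over qualifying years
  cross <- ok & a1 != a2 & y1 == y2
  yrs <- table(y1[cross])
  good_years <- as.integer(names(yrs)[yrs >= min_pairs])
  bsel <- cross & y1 %in% good_years
  if (!any(bsel)) stop_cfg("no cross-area same-year pairs for the baseline")
  baseline <- mean(v[bsel])
  bw <- pair_boot_weights(as.character(pairs$id_a[bsel]),
                          as.character(pairs$id_b[bsel]), max(n_boot, 1))
  brep <- vapply(bw, function(w) stats::weighted.mean(v[bsel], w), numeric(1))
  a <- (1 - conf) / 2
  base_ci <- stats::quantile(brep, c(a, 1 - a), na.rm = TRUE)

  one_area <- function(lab) {
    insel <- ok & !is.na(a1) & !is.na(a2) & a1 == lab & a2 == lab
    lag <- abs(y1 - y2)[insel]
    if (!any(insel)) stop_cfg("no within-area pairs in area '%s'", lab)
    ml <- if (is.null(max_lag)) max(lag) else max_lag
    keep <- lag <= ml
    vv <- v[insel][keep]; ll <- lag[keep]
    pa <- as.character(pairs$id_a[insel])[keep]
    pb <- as.character(pairs$id_b[insel])[keep]
    lags <- 0:ml
    mu <- n <- lo <- hi <- rep(NA_real_, length(lags))
    for (i in seq_along(lags)) {
      s <- ll == lags[i]
      n[i] <- sum(s)
      if (!n[i]) next
      mu[i] <- mean(vv[s])
      if (n_boot > 0) {
        W <- pair_boot_weights(pa[s], pb[s], n_boot)
        reps <- vapply(W, function(w)
          if (any(w > 0)) stats::weighted.mean(vv[s], w) else NA_real_,
          numeric(1))
        qq <- stats::quantile(reps, c(a, 1 - a), na.rm = TRUE)
        lo[i] <- qq[[1]]; hi[i] <- qq[[2]]
      }
    }
    tab <- data.frame(lag_years = lags, mean = mu, lo = lo, hi = hi,
                      n_pairs = as.integer(n), sparse = n < min_pairs)
    # crossing: the smallest lag L at which the curve has become
    # indistinguishable from the baseline, requiring both (i) the lag-L bin
    # itself is not significantly above baseline (its CI lower bound does not
    # exceed it) and (ii) the pooled pairs of the forward window of lags
    # L..L+4 are not significantly above baseline. The per-lag condition
    # stops under-powered early bins from counting as crossed; the pooled
    # forward window stops a single noisy bin from deciding either way.
    elevated_bin <- !is.na(lo) & lo > baseline
    has_data <- !is.na(mu)
    tail_elevated <- function(i) {
      s <- ll >= lags[i] & ll <= lags[i] + 4
      if (sum(s) < 2) return(FALSE)
      W <- pair_boot_weights(pa[s], pb[s], max(n_boot, 1))
      reps <- vapply(W, function(w)
        if (any(w > 0)) stats::weighted.mean(vv[s], w) else NA_real_,
        numeric(1))
      stats::quantile(reps, (1 - conf) / 2, na.rm = TRUE) > baseline
    }
    crossing <- NA_integer_
    for (i in seq_along(lags)) {
      if (has_data[i] && !elevated_bin[i] && !tail_elevated(i)) {
        crossing <- lags[i]; break
      }
    }
    list(table = tab, crossing_lag = crossing)
  }
  res_a <- one_area("a"); res_b <- one_area("b")
  structure(list(
    area_a = res_a$table, area_b = res_b$table,
    baseline = baseline, baseline_ci = unname(base_ci),
    crossing_lag = c(a = res_a$crossing_lag, b = res_b$crossing_lag),
    n_baseline_pairs = sum(bsel)
  ), class = "lag_curves")
}

#' @export
print.lag_curves <- function(x, ...) {
  cat(sprintf("Cohort-lag relatedness curves; baseline %.5f [%.5f, %.5f] (n = %d)\n",
              x$baseline, x$baseline_ci[1], x$baseline_ci[2], x$n_baseline_pairs))
  cat(sprintf("  crossing lag: area a = %s, area b = %s years\n",
              x$crossing_lag["a"], x$crossing_lag["b"]))
  invisible(x)
}

#' @export
plot.lag_curves <- function(x, ...) {
  yl <- range(c(x$area_a$mean, x$area_b$mean, x$baseline), na.rm = TRUE)
  plot(x$area_a$lag_years, x$area_a$mean, type = "b", pch = 20, ylim = yl,
       xlab = "birth-year lag", ylab = "mean relatedness", ...)
  graphics::lines(x$area_b$lag_years, x$area_b$mean, type = "b", pch = 1,
                  col = "grey40")
  graphics::abline(h = x$baseline, lty = 2)
  graphics::legend("topright", c("area a", "area b", "baseline"),
                   pch = c(20, 1, NA), lty = c(1, 1, 2),
                   col = c("black", "grey40", "black"), bty = "n")
  invisible(x)
}
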