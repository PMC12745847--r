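#' Construct a nestbox map
#'
#' @param boxes a data frame with columns `box_id`, `x`, `y` (metres).
#' @return an object of class `nestbox_map`: the data frame with a
#'   `woodland_extent` attribute (maximum pairwise box distance).
#' @export
nestbox_map <- function(boxes) {
  stopifnot(is.data.frame(boxes), all(c("box_id", "x", "y") %in% names(boxes)))
  if (nrow(boxes) < 2) stop_cfg("a nestbox map needs at least 2 boxes")
  if (anyDuplicated(boxes$box_id)) stop_cfg("box_ids must be unique")
  if (!all(is.finite(boxes$x)) || !all(is.finite(boxes$y)))
    stop_cfg("box coordinates must be finite")
  boxes <- boxes[order(boxes$box_id), c("box_id", "x", "y")]
  rownames(boxes) <- NULL
  attr(boxes, "woodland_extent") <- max_pairwise_distance(boxes$x, boxes$y)
  class(boxes) <- c("nestbox_map", "data.frame")
  boxes
}

#' Woodland extent of a nestbox map
#' @param map a `nestbox_map`.
#' @return maximum pairwise box distance in metres.
#' @export
woodland_extent <- function(map) attr(map, "woodland_extent")

#' Place nestboxes in a synthetic woodland
#'
#' Boxes are laid out by jittered-grid (blue-noise-like) sampling inside a
#' circular woodland, then rescaled so that the realized maximum pairwise box
#' distance equals `config$extent_m` exactly. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param use_seed seed the RNG from `config$seed` (set `FALSE` when the
#'   caller already controls the RNG stream).
#' @return a [nestbox_map()].
#' @export
build_landscape <- function(config, use_seed = TRUE) {
  validate_sim_config(config)
  n <- config$n_boxes
  R <- config$extent_m / 2
  gen <- function() {
    # grid fine enough that the disc holds > n candidate cells
    s <- sqrt(pi * R^2 / n) * 0.92
    gx <- seq(-R, R, by = s)
    pts <- expand.grid(x = gx, y = gx)
    pts$x <- pts$x + stats::runif(nrow(pts), -0.45 * s, 0.45 * s)
    pts$y <- pts$y + stats::runif(nrow(pts), -0.45 * s, 0.45 * s)
    pts <- pts[pts$x^2 + pts$y^2 <= R^2, ]
    while (nrow(pts) < n) {
      extra <- data.frame(x = stats::runif(n, -R, R), y = stats::runif(n, -R, R))
      extra <- extra[extra$x^2 + extra$y^2 <= R^2, ]
      pts <- rbind(pts, extra)
    }
    pts[sample.int(nrow(pts), n), ]
  }
  pts <- if (use_seed) with_seed(config$seed, gen()) else gen()
  # rescale so the realized diameter equals the configured extent
  d <- max_pairwise_distance(pts$x, pts$y)
  pts$x <- pts$x * config$extent_m / d
  pts$y <- pts$y * config$extent_m / d
  nestbox_map(data.frame(box_id = seq_len(n), x = pts$x, y = pts$y))
}

#' @export
print.nestbox_map <- function(x, ...) {
  cat(sprintf("Nestbox map: %d boxes, extent %.0f m\n",
              nrow(x), woodland_extent(x)))
  invisible(x)
}

#' @export
plot.nestbox_map <- function(x, ...) {
  plot(x$x, x$y, pch = 20, cex = 0.5, asp = 1,
       xlab = "x (m)", ylab = "y (m)", main = "Nestbox map", ...)
  invisible(x)
}
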