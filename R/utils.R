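`%||%` <- function(a, b) if (is.null(a)) b else a

#' Euclidean distance between two points or point sets
#' @noRd
euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

#' Maximum pairwise distance of a point cloud.
#'
#' Uses the convex hull first: the diameter of a finite point set is attained
#' between hull vertices.
#' @noRd
max_pairwise_distance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(x) > 3) {
    h <- grDevices::chull(x, y)
    x <- x[h]; y <- y[h]
  }
  d <- stats::dist(cbind(x, y))
  max(d)
}

#' Run code with a locally seeded RNG, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Stable per-purpose sub-seed derived from a master seed.
#' @noRd
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 100000L) * 10000L + as.integer(k) %% 10000L
}

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)
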