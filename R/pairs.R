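# Pair-level annotation: breeding/natal distances, pair type, sex pair.

#' Long breeding-record table of a simulation
#'
#' @param sim a `woodsim`.
#' @return data frame `id`, `year`, `box_id`, one row per breeder-year.
#' @export
breeding_records <- function(sim) {
  b <- sim$breeding
  rbind(data.frame(id = b$male_id, year = b$year, box_id = b$box_id),
        data.frame(id = b$female_id, year = b$year, box_id = b$box_id))
}

#' Annotate pairs with distances, pair type and sex pair
#'
#' Breeding distance between two individuals uses boxes occupied in a common
#' breeding year (minimum over common years); pairs that never co-bred fall
#' back to the minimum distance across breeding-year combinations at most
#' `max_year_gap` years apart, and are otherwise excluded (distance `NA`).
#' Natal distance is defined only when both natal boxes are known, so any
#' pair involving an immigrant has `natal_distance_m = NA`.
#'
#' @param pairs data frame with `id_a`, `id_b` (e.g., from [mom_ibd()] or
#'   [king_robust()]).
#' @param samples sample metadata with `id`, `sex`, `status`, `natal_box`.
#' @param breeding long breeding records (`id`, `year`, `box_id`), e.g., from
#'   [breeding_records()].
#' @param locations box coordinates (`box_id`, `x`, `y`), e.g., a
#'   [nestbox_map()].
#' @param max_year_gap largest breeding-year gap used for pairs that never
#'   co-bred.
#' @return `pairs` with columns `breeding_distance_m`, `natal_distance_m`,
#'   `pair_type` (`local-local` / `local-immigrant` /
#'   `immigrant-immigrant`), `sex_pair` (`MM`/`MF`/`FF`), `year_a`, `year_b`.
#'   The number of pairs excluded for missing coordinates is attached as
#'   attribute `n_excluded`.
#' @export
pair_table <- function(pairs, samples, breeding, locations, max_year_gap = 2) {
  samples$id <- as.character(samples$id)
  breeding$id <- as.character(breeding$id)
  loc <- as.data.frame(locations)
  bi <- match(breeding$box_id, loc$box_id)
  rec <- data.frame(id = breeding$id, year = breeding$year,
                    x = loc$x[bi], y = loc$y[bi], stringsAsFactors = FALSE)
  rid <- split(seq_len(nrow(rec)), rec$id)
  np <- nrow(pairs)
  ia_l <- rid[as.character(pairs$id_a)]
  ib_l <- rid[as.character(pairs$id_b)]
  la <- lengths(ia_l); lb <- lengths(ib_l)
  pr <- rep(seq_len(np), la * lb)
  # cartesian expansion of record combinations per pair, fully vectorised
  Ai <- rep(unlist(ia_l, use.names = FALSE), times = rep(lb, la))
  Bi <- unlist(ib_l[rep(seq_len(np), la)], use.names = FALSE)
  dy <- abs(rec$year[Ai] - rec$year[Bi])
  dd <- euclid(rec$x[Ai], rec$y[Ai], rec$x[Bi], rec$y[Bi])
  prio <- ifelse(dy == 0, 0L, ifelse(dy <= max_year_gap, 1L, 2L))
  o <- order(pr, prio, dd)
  first <- o[!duplicated(pr[o])]
  bd <- rep(NA_real_, np)
  got <- pr[first]
  val <- ifelse(prio[first] <= 1L, dd[first], NA_real_)
  bd[got] <- val

  sa <- match(as.character(pairs$id_a), samples$id)
  sb <- match(as.character(pairs$id_b), samples$id)
  nb_a <- samples$natal_box[sa]; nb_b <- samples$natal_box[sb]
  xa <- loc$x[match(nb_a, loc$box_id)]; ya <- loc$y[match(nb_a, loc$box_id)]
  xb <- loc$x[match(nb_b, loc$box_id)]; yb <- loc$y[match(nb_b, loc$box_id)]
  nd <- euclid(xa, ya, xb, yb)

  st <- cbind(samples$status[sa], samples$status[sb])
  n_imm <- rowSums(st == "immigrant")
  pair_type <- c("local-local", "local-immigrant",
                 "immigrant-immigrant")[n_imm + 1L]
  sx <- cbind(samples$sex[sa], samples$sex[sb])
  n_m <- rowSums(sx == "M")
  sex_pair <- c("FF", "MF", "MM")[n_m + 1L]

  year_first <- vapply(rid, function(i) min(rec$year[i]), numeric(1))
  pairs$breeding_distance_m <- bd
  pairs$natal_distance_m <- nd
  pairs$pair_type <- pair_type
  pairs$sex_pair <- sex_pair
  pairs$year_a <- unname(year_first[as.character(pairs$id_a)])
  pairs$year_b <- unname(year_first[as.character(pairs$id_b)])
  attr(pairs, "n_excluded") <- sum(is.na(bd))
  pairs
}

#' Remove close kin from a pair table
#'
#' Progressive kin stripping, either by SNP-based kinship degree (the
#' `degree` column from [king_robust()]) or by social-pedigree links
#' (parent-offspring and full siblings, optionally half siblings).
#'
#' @param pairs annotated pair table.
#' @param level `"none"`, `"no_first"` (drop duplicates and first-degree),
#'   `"no_first_second"`, or `"distant_only"` (keep only pairs beyond third
#'   degree).
#' @param source `"snp_degree"` or `"social_pedigree"`.
#' @param pedigree pedigree data frame (`id`, `dam`, `sire`) required for the
#'   social-pedigree source.
#' @param drop_half_sibs also drop social half siblings (pedigree source).
#' @return the filtered pair table.
#' @export
strip_kin <- function(pairs,
                      level = c("none", "no_first", "no_first_second",
                                "distant_only"),
                      source = c("snp_degree", "social_pedigree"),
                      pedigree = NULL, drop_half_sibs = FALSE) {
  level <- match.arg(level)
  source <- match.arg(source)
  if (level == "none") return(pairs)
  if (source == "snp_degree") {
    if (is.null(pairs$degree)) stop_cfg("pairs lack a 'degree' column")
    drop_lv <- switch(level,
      no_first = c("duplicate", "first"),
      no_first_second = c("duplicate", "first", "second"),
      distant_only = c("duplicate", "first", "second", "third"))
    return(pairs[!(pairs$degree %in% drop_lv), , drop = FALSE])
  }
  if (is.null(pedigree)) stop_cfg("social-pedigree stripping needs 'pedigree'")
  pd <- pedigree
  pid <- as.character(pd$id)
  dam <- stats::setNames(as.character(pd$dam), pid)
  sire <- stats::setNames(as.character(pd$sire), pid)
  a <- as.character(pairs$id_a); b <- as.character(pairs$id_b)
  eq <- function(x, y) !is.na(x) & x == y
  po <- eq(dam[a], b) | eq(sire[a], b) | eq(dam[b], a) | eq(sire[b], a)
  share_dam <- !is.na(dam[a]) & !is.na(dam[b]) & dam[a] == dam[b]
  share_sire <- !is.na(sire[a]) & !is.na(sire[b]) & sire[a] == sire[b]
  fs <- share_dam & share_sire
  hs <- xor(share_dam, share_sire)
  drop <- po | fs
  if (drop_half_sibs) drop <- drop | hs
  pairs[!drop, , drop = FALSE]
}
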