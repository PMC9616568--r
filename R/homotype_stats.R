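# Per-homotype bundling, packing and overlap statistics.
#
# d_intra(X): mean inter-PN distance over all unordered pairs of uPNs inside
# homotype X (the tightness of bundling; undefined for single-uPN homotypes,
# the "asterisk" convention). d_inter(X): mean distance over all cross pairs
# between X and every other homotype (the extent of packing around X).
# lambda(X) = d_intra(X) / d_inter(X) is the degree of overlapping; lambda
# well below 1 (the descriptive threshold is 0.4) marks a tightly bundled,
# segregated homotype.

submatrix_values <- function(d, rows, cols) {
  unclass(d)[rows, cols, drop = FALSE]
}

check_members <- function(d, members, what) {
  missing <- setdiff(members, rownames(d))
  assert_that(!length(missing), "%s not in distance matrix: %s", what,
              paste(missing, collapse = ", "))
}

#' Mean intra-homotype distance
#'
#' @param d a `pn_distance_matrix`.
#' @param members neuron ids of one homotype (subset of the matrix labels).
#' @return mean distance over all unordered member pairs, or `NA` when the
#'   homotype has fewer than two members (undefined, flagged downstream).
#' @export
intra_homotype <- function(d, members) {
  check_members(d, members, "members")
  if (length(members) < 2L) return(NA_real_)
  v <- submatrix_values(d, members, members)
  mean(v[upper.tri(v)])
}

#' Mean inter-homotype distance
#'
#' @param d a `pn_distance_matrix`.
#' @param members neuron ids of the homotype of interest.
#' @param others neuron ids of all other homotypes (disjoint from `members`).
#' @return mean distance over all cross pairs.
#' @export
inter_homotype <- function(d, members, others) {
  check_members(d, members, "members")
  check_members(d, others, "others")
  assert_that(length(members) >= 1L && length(others) >= 1L,
              "members and others must both be non-empty")
  overlap <- intersect(members, others)
  assert_that(!length(overlap), "members and others overlap: %s",
              paste(overlap, collapse = ", "))
  mean(submatrix_values(d, members, others))
}

#' Degree of overlapping
#'
#' @param d_intra mean intra-homotype distance (may be `NA` when undefined).
#' @param d_inter mean inter-homotype distance; must be positive.
#' @return `d_intra / d_inter`; `NA` propagates from an undefined `d_intra`.
#' @export
lambda_x <- function(d_intra, d_inter) {
  assert_that(is.numeric(d_inter) && length(d_inter) == 1L && !is.na(d_inter),
              "d_inter must be a number")
  assert_that(d_inter > 0, "d_inter is zero: coincident populations")
  if (is.na(d_intra)) return(NA_real_)
  d_intra / d_inter
}

#' Per-homotype statistics table for one neuropil
#'
#' @param d a `pn_distance_matrix` for one neuropil.
#' @param annotations a `neuron_table` covering the matrix neurons.
#' @param lambda_threshold descriptive bundling threshold used for the `bundled`
#'   flag (default 0.4).
#' @return data frame with columns `homotype`, `neuropil`, `n`, `d_intra`,
#'   `d_inter`, `lambda`, `flag` (`"*"` marks single-uPN homotypes whose
#'   intra-homotype distance is unavailable) and `bundled`
#'   (`lambda < lambda_threshold`, `NA` when lambda is undefined).
#' @export
homotype_stats <- function(d, annotations, lambda_threshold = 0.4) {
  validate_distance_matrix(d)
  assert_that(inherits(annotations, "neuron_table"), "annotations must be a neuron_table")
  ids <- rownames(d)
  missing <- setdiff(ids, annotations$neuron_id)
  assert_that(!length(missing), "matrix neurons missing from annotations: %s",
              paste(missing, collapse = ", "))
  homo <- annotations$homotype[match(ids, annotations$neuron_id)]
  types <- sort(unique(homo))
  out <- lapply(types, function(X) {
    members <- ids[homo == X]
    others <- ids[homo != X]
    di <- intra_homotype(d, members)
    de <- if (length(others)) inter_homotype(d, members, others) else NA_real_
    lam <- if (is.na(de)) NA_real_ else lambda_x(di, de)
    data.frame(homotype = X, neuropil = attr(d, "neuropil") %||% NA_character_,
               n = length(members), d_intra = di, d_inter = de, lambda = lam,
               flag = if (length(members) == 1L) "*" else "",
               bundled = if (is.na(lam)) NA else lam < lambda_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Population summary over homotypes
#'
#' Averages (and standard deviations) of `d_intra`, `d_inter` and `lambda`
#' over homotypes, computed only over homotypes where the quantity is defined
#' (single-uPN homotypes drop out of the `d_intra` and `lambda` means).
#'
#' @param stats per-homotype table from [homotype_stats()].
#' @return one-row data frame with means, standard deviations and the number
#'   of homotypes entering each average.
#' @export
population_summary <- function(stats) {
  assert_that(is.data.frame(stats) && all(c("d_intra", "d_inter", "lambda") %in% names(stats)),
              "stats must be a homotype_stats() table")
  msd <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_, n = length(v))
  }
  a <- msd(stats$d_intra); b <- msd(stats$d_inter); l <- msd(stats$lambda)
  data.frame(neuropil = stats$neuropil[1],
             d_intra_mean = a["mean"], d_intra_sd = a["sd"], n_intra = a["n"],
             d_inter_mean = b["mean"], d_inter_sd = b["sd"], n_inter = b["n"],
             lambda_mean = l["mean"], lambda_sd = l["sd"], n_lambda = l["n"],
             row.names = NULL)
}

#' Correlation of the degree of overlapping between two neuropils
#'
#' Pearson correlation of per-homotype lambda values over the homotypes with a
#' defined lambda in both neuropils (single-uPN homotypes are excluded by the
#' undefined-lambda convention), with the two-sided t-distribution p-value.
#'
#' @param stats_a,stats_b per-homotype tables from [homotype_stats()].
#' @return list with `r`, `p`, `n` (common homotypes) and `homotypes`.
#' @export
lambda_correlation <- function(stats_a, stats_b) {
  common <- intersect(stats_a$homotype[!is.na(stats_a$lambda)],
                      stats_b$homotype[!is.na(stats_b$lambda)])
  assert_that(length(common) >= 3L,
              "need at least 3 homotypes with lambda defined in both neuropils (found %d)",
              length(common))
  x <- stats_a$lambda[match(common, stats_a$homotype)]
  y <- stats_b$lambda[match(common, stats_b$homotype)]
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common), homotypes = common)
}

#' Write a per-homotype statistics table as delimited text
#'
#' @param stats table from [homotype_stats()] (or several `rbind`-ed).
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_homotype_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
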