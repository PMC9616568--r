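# PN -> third-order-neuron interface analysis: thresholded binarization,
# homotype-specific connection counts, common-synapse matrices, cosine-
# distance connectivity clustering, and tanglegram congruence statistics.

#' Read a weighted bipartite synapse table
#'
#' Delimited text with columns `pre_id` (uPN), `post_id` (third-order neuron),
#' optional `interface` (`PN-KC` / `PN-LHN`) and `weight` (synapse count).
#' One record per (pre, post, interface) is enforced.
#'
#' @param path path to a comma- or tab-separated file (sniffed from header).
#' @return a validated data frame.
#' @export
read_synapse_table <- function(path) {
  assert_that(file.exists(path), "synapse table not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  synapse_table(df)
}

#' Validate a synapse table
#'
#' @param df data frame with columns `pre_id`, `post_id`, `weight` and
#'   optionally `interface`.
#' @return the validated data frame (ids as character, weights as integer).
#' @export
synapse_table <- function(df) {
  required <- c("pre_id", "post_id", "weight")
  assert_that(is.data.frame(df) && all(required %in% names(df)),
              "synapse table must have columns %s", paste(required, collapse = ", "))
  if (!"interface" %in% names(df)) df$interface <- NA_character_
  df$pre_id <- as.character(df$pre_id)
  df$post_id <- as.character(df$post_id)
  assert_that(all(df$weight >= 0) && all(df$weight == round(df$weight)),
              "synapse weights must be non-negative integers")
  key <- paste(df$pre_id, df$post_id, df$interface, sep = "\r")
  assert_that(!anyDuplicated(key),
              "duplicate (pre_id, post_id, interface) record in synapse table")
  df[c("pre_id", "post_id", "interface", "weight")]
}

#' Binarize a synapse table into a connectivity matrix
#'
#' The threshold applies per (uPN, partner) pair: a pair is connected when its
#' synapse count reaches `threshold` (the partner-inclusion rule; default 3,
#' with 8 as the stringent robustness setting). At `level = "homotype"` an
#' edge exists between homotype X and partner i when any member uPN meets the
#' threshold; partner columns with no retained edge are dropped. At
#' `level = "upn"` rows are individual uPNs (used for connectivity-based
#' clustering). Rows and columns are sorted for determinism.
#'
#' @param table synapse table (see [synapse_table()]).
#' @param threshold minimum per-pair synapse count (>= 1).
#' @param homotype_map named character vector mapping uPN id -> homotype
#'   (or a `neuron_table`).
#' @param interface optional interface tag to filter on (`"PN-KC"`, `"PN-LHN"`).
#' @param level `"homotype"` (default) or `"upn"` rows.
#' @return binary 0/1 matrix with attributes `threshold`, `interface`, `level`
#'   and (for `level = "upn"`) `homotypes` (row-aligned homotype labels).
#' @export
binarize_synapses <- function(table, threshold = 3L, homotype_map,
                              interface = NULL, level = c("homotype", "upn")) {
  level <- match.arg(level)
  assert_that(is_count(threshold), "threshold must be a positive integer")
  df <- synapse_table(table)
  if (!is.null(interface)) df <- df[df$interface %in% interface, , drop = FALSE]
  if (inherits(homotype_map, "neuron_table")) {
    homotype_map <- stats::setNames(homotype_map$homotype, homotype_map$neuron_id)
  }
  unknown <- setdiff(unique(df$pre_id), names(homotype_map))
  assert_that(!length(unknown), "uPN(s) without homotype annotation: %s",
              paste(utils::head(sort(unknown), 5L), collapse = ", "))
  df <- df[df$weight >= threshold, , drop = FALSE]
  rows <- if (level == "homotype") unname(homotype_map[df$pre_id]) else df$pre_id
  rlab <- sort(unique(rows))
  clab <- sort(unique(df$post_id))
  m <- matrix(0L, length(rlab), length(clab), dimnames = list(rlab, clab))
  if (nrow(df)) m[cbind(match(rows, rlab), match(df$post_id, clab))] <- 1L
  attr(m, "threshold") <- as.integer(threshold)
  attr(m, "interface") <- if (is.null(interface)) NA_character_ else interface
  attr(m, "level") <- level
  if (level == "upn") attr(m, "homotypes") <- unname(homotype_map[rlab])
  m
}

#' Homotype-specific connection counts
#'
#' For each homotype X: `N_tot` is the number of third-order neurons connected
#' to X (row sum of the binary matrix), `N_sp` counts the partners connected
#' to X and to no other homotype, and `f = N_sp / N_tot` is the specific
#' fraction (undefined when `N_tot = 0`).
#'
#' @param C binary homotype x partner connectivity matrix from
#'   [binarize_synapses()].
#' @return data frame with columns `homotype`, `n_sp`, `n_tot`, `f`.
#' @export
specificity <- function(C) {
  m <- as.matrix(C)
  assert_that(all(m %in% c(0L, 1L)), "connectivity matrix must be binary")
  ntot <- rowSums(m)
  exclusive <- colSums(m) == 1L
  nsp <- as.integer(rowSums(m[, exclusive, drop = FALSE]))
  data.frame(homotype = rownames(m) %||% as.character(seq_len(nrow(m))),
             n_sp = nsp, n_tot = as.integer(ntot),
             f = ifelse(ntot > 0, nsp / ntot, NA_real_),
             stringsAsFactors = FALSE)
}

#' Common synapse matrix
#'
#' `S[X, Y]` counts the third-order neurons connected to both homotypes X and
#' Y; the diagonal equals each homotype's total partner count. Computed by
#' explicit shared-partner counting (tests check it against the `C %*% t(C)`
#' matrix-product oracle).
#'
#' @param C binary homotype x partner connectivity matrix.
#' @return symmetric integer matrix over homotypes.
#' @export
common_synapses <- function(C) {
  m <- as.matrix(C)
  assert_that(all(m %in% c(0L, 1L)), "connectivity matrix must be binary")
  n <- nrow(m)
  s <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (x in seq_len(n)) {
    s[x, x] <- sum(m[x, ] == 1L)
    if (x < n) {
      for (y in (x + 1L):n) {
        shared <- sum(m[x, ] == 1L & m[y, ] == 1L)
        s[x, y] <- shared
        s[y, x] <- shared
      }
    }
  }
  s
}

#' Cosine distance between two connectivity rows
#'
#' `1 - (u . v) / (|u| |v|)`, in `[0, 2]`.
#'
#' @param u,v numeric vectors of equal length; neither may be all-zero.
#' @return the cosine distance.
#' @export
cosine_distance <- function(u, v) {
  assert_that(length(u) == length(v), "vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  assert_that(nu > 0 && nv > 0, "cosine distance undefined for a zero vector")
  1 - sum(u * v) / (nu * nv)
}

cosine_distance_matrix <- function(m) {
  norms <- sqrt(rowSums(m^2))
  cm <- tcrossprod(m / norms)
  d <- 1 - cm
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Connectivity-based clustering of uPNs
#'
#' Ward agglomeration (the variance-minimising criterion, `ward.D2`) on
#' pairwise cosine distances between per-uPN binary connectivity rows.
#' All-zero rows are excluded with a warning.
#'
#' @param C binary uPN x partner matrix from
#'   `binarize_synapses(..., level = "upn")`.
#' @return an `hclust` over the retained uPNs.
#' @export
connectivity_clustering <- function(C) {
  m <- as.matrix(C)
  assert_that(all(m %in% c(0L, 1L)), "connectivity matrix must be binary")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warn_("excluding %d uPN(s) with no retained connections: %s", sum(zero),
          paste(utils::head(rownames(m)[zero], 5L), collapse = ", "))
    m <- m[!zero, , drop = FALSE]
  }
  assert_that(nrow(m) >= 2L, "need at least 2 uPNs with non-zero rows")
  d <- cosine_distance_matrix(m)
  stats::hclust(stats::as.dist(d), method = "ward.D2")
}

# --- tanglegram machinery ---------------------------------------------------

# For every leaf pair, the highest cluster count k at which the pair already
# shares a cluster under cutree(tree, k); k = n - (depth of merge). Vector is
# ordered over the upper triangle of the (sorted) label pairs.
cocluster_ranks <- function(tree, labels_sorted) {
  n <- length(tree$labels)
  merged_at <- matrix(0L, n, n, dimnames = list(tree$labels, tree$labels))
  info <- tree_children_info(tree)
  for (k in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[k, ]
    set1 <- if (kids[1] < 0) -kids[1] else info$leafsets[[kids[1]]]
    set2 <- if (kids[2] < 0) -kids[2] else info$leafsets[[kids[2]]]
    # pairs united at merge k first co-cluster when n - k clusters remain
    merged_at[set1, set2] <- n - k
    merged_at[set2, set1] <- n - k
  }
  m <- merged_at[labels_sorted, labels_sorted]
  m[upper.tri(m)]
}

# Reorder tree2's subtrees so leaves follow tree1's leaf order as closely as
# the topology allows (greedy one-sided untangling: each internal node orders
# its children by the mean target rank of their leaves).
untangle_step1side <- function(tree1, tree2) {
  target <- stats::setNames(seq_along(tree1$labels[tree1$order]),
                            tree1$labels[tree1$order])
  wts <- as.numeric(target[tree2$labels])
  dend <- stats::reorder(stats::as.dendrogram(tree2), wts, agglo.FUN = mean)
  ord <- stats::order.dendrogram(dend)
  tree2$order <- ord
  tree2
}

#' Tanglegram congruence statistics for two dendrograms
#'
#' Baker's Gamma (Spearman rank correlation between, over all leaf pairs, the
#' number of clusters at which the pair first co-clusters in each tree),
#' entanglement (normalised sum of squared leaf-rank differences after greedy
#' one-sided `step1side` untangling: tree 1's leaf order is fixed and tree 2's
#' internal nodes are rotated towards it; the normaliser is the fully reversed
#' order), and the Pearson correlation of the two cophenetic distance
#' matrices.
#'
#' @param t1,t2 `hclust` objects over identical leaf sets.
#' @param untangle apply `step1side` rotation before the entanglement score
#'   (default TRUE).
#' @return list with `bakers_gamma`, `entanglement`, `cophenetic_r`.
#' @export
tanglegram_stats <- function(t1, t2, untangle = TRUE) {
  assert_that(inherits(t1, "hclust") && inherits(t2, "hclust"),
              "t1 and t2 must be hclust objects")
  assert_that(setequal(t1$labels, t2$labels) &&
                length(t1$labels) == length(t2$labels),
              "trees must share an identical leaf set")
  labels_sorted <- sort(t1$labels)
  n <- length(labels_sorted)
  assert_that(n >= 3L, "need at least 3 leaves")
  g1 <- cocluster_ranks(t1, labels_sorted)
  g2 <- cocluster_ranks(t2, labels_sorted)
  gamma <- stats::cor(g1, g2, method = "spearman")
  if (untangle) t2 <- untangle_step1side(t1, t2)
  r1 <- stats::setNames(seq_len(n), t1$labels[t1$order])
  r2 <- stats::setNames(seq_len(n), t2$labels[t2$order])
  num <- sum((r1[labels_sorted] - r2[labels_sorted])^2)
  worst <- sum((seq_len(n) - rev(seq_len(n)))^2)
  c1 <- as.matrix(stats::cophenetic(t1))[labels_sorted, labels_sorted]
  c2 <- as.matrix(stats::cophenetic(t2))[labels_sorted, labels_sorted]
  list(bakers_gamma = gamma,
       entanglement = num / worst,
       cophenetic_r = stats::cor(c1[upper.tri(c1)], c2[upper.tri(c2)]))
}

#' Permutation null for a tanglegram statistic
#'
#' Permutes the leaf labels of the second tree `n_perm` times and reports
#' `p = (1 + #{stat_perm >= stat_obs}) / (n_perm + 1)` for the chosen
#' congruence index (a seeded stand-in for a full statistical calibration of
#' the indices).
#'
#' @param t1,t2 `hclust` objects over identical leaf sets.
#' @param stat one of `"bakers_gamma"`, `"cophenetic_r"`.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return list with `p`, `observed`, `n_perm`.
#' @export
tanglegram_null <- function(t1, t2, stat = c("bakers_gamma", "cophenetic_r"),
                            n_perm = 200L, seed = NULL) {
  stat <- match.arg(stat)
  if (!is.null(seed)) set.seed(seed)
  obs <- tanglegram_stats(t1, t2, untangle = FALSE)[[stat]]
  hits <- 0L
  for (k in seq_len(n_perm)) {
    perm <- t2
    perm$labels <- sample(t2$labels)
    if (tanglegram_stats(t1, perm, untangle = FALSE)[[stat]] >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  list(p = (1 + hits) / (n_perm + 1), observed = obs, n_perm = n_perm)
}

#' Export a labelled matrix as CSV
#'
#' Shared exporter for connectivity and common-synapse matrices.
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labelled_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
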