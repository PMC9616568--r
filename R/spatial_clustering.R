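# Hierarchical clustering of neurons from a distance matrix, with the dynamic
# hybrid tree cut as default and three alternative cut criteria (elbow, gap
# statistic, maximum mean silhouette).

#' Complete-linkage dendrogram from a distance matrix
#'
#' Farthest-point agglomeration on the inter-PN distances. Complete linkage
#' guarantees monotone merge heights, and operates on the dissimilarities as
#' given (the inter-PN distance need not satisfy the triangle inequality).
#'
#' @param d a `pn_distance_matrix` (square, symmetric, zero diagonal).
#' @return an `hclust` object with the neuron ids as labels.
#' @export
complete_linkage <- function(d) {
  validate_distance_matrix(d)
  stats::hclust(stats::as.dist(unclass(d)), method = "complete")
}

# hclust bookkeeping: heights of the two children of each internal node
# (0 for leaves), the leaf set and the internal-merge index set under each
# internal node.
tree_children_info <- function(tree) {
  n <- length(tree$labels %||% tree$order)
  m <- nrow(tree$merge)
  leafsets <- vector("list", m)
  mergesets <- vector("list", m)
  child_height <- matrix(0, m, 2L)
  for (k in seq_len(m)) {
    kids <- tree$merge[k, ]
    sets <- lapply(kids, function(c) if (c < 0) -c else leafsets[[c]])
    leafsets[[k]] <- c(sets[[1]], sets[[2]])
    msets <- lapply(kids, function(c) if (c < 0) integer(0) else mergesets[[c]])
    mergesets[[k]] <- c(msets[[1]], msets[[2]], k)
    child_height[k, ] <- ifelse(kids < 0, 0, tree$height[pmax(kids, 1L)])
  }
  list(leafsets = leafsets, mergesets = mergesets,
       child_height = child_height, n = n)
}

#' Dynamic hybrid tree cut
#'
#' Adaptive dendrogram cutting with a minimum cluster size. Each branch is
#' decomposed recursively at the largest multiplicative gap in its sorted
#' merge heights: when consecutive heights jump by at least `ratio` (mapped
#' from `deep_split`, 0..4 giving 4, 3, 2.2, 1.8, 1.5; larger `deep_split`
#' splits deeper), the merges above the gap are junction levels and the
#' subtrees hanging below them become sub-branches. A gap is only accepted
#' when it yields at least two components of `min_cluster_size` or more, so
#' tight bundles are not shredded into fragments. Branches smaller than
#' `min_cluster_size` are dissolved and, in the PAM-like stage, their leaves
#' are re-assigned to the qualifying cluster with the smallest mean
#' dissimilarity. Deterministic given the tree (ties go to the lower cluster
#' index).
#'
#' @param tree an `hclust` from [complete_linkage()] (any monotone linkage works).
#' @param d the distance matrix used to build `tree`; required for the PAM
#'   stage (stray-leaf assignment).
#' @param min_cluster_size minimum members per cluster (default 4).
#' @param deep_split split sensitivity, integer 0..4 (default 2).
#' @param pam_stage assign stray leaves to the nearest qualifying cluster
#'   (default TRUE). With `FALSE` strays keep label 0 ("unassigned").
#' @param fallback what to do when no branch qualifies (including n <
#'   `min_cluster_size`): `"single"` puts everything in one cluster,
#'   `"unassigned"` labels everything 0.
#' @return named integer vector of cluster labels (1-based; 0 = unassigned)
#'   with attributes `method` and `params`.
#' @export
cut_dynamic_hybrid <- function(tree, d = NULL, min_cluster_size = 4L,
                               deep_split = 2L, pam_stage = TRUE,
                               fallback = c("single", "unassigned")) {
  assert_that(inherits(tree, "hclust"), "tree must be an hclust object")
  assert_that(is_count(min_cluster_size), "min_cluster_size must be a positive integer")
  assert_that(deep_split %in% 0:4, "deep_split must be an integer in 0..4")
  fallback <- match.arg(fallback)
  ratio <- c(4, 3, 2.2, 1.8, 1.5)[deep_split + 1L]
  info <- tree_children_info(tree)
  n <- info$n
  labels <- tree$labels %||% as.character(seq_len(n))

  candidates <- list()
  comp_size <- function(k) if (k < 0) 1L else length(info$leafsets[[k]])
  # subtrees of node k whose top merge lies below cut_level
  collect_components <- function(k, cut_level) {
    comps <- list()
    rec <- function(k) {
      if (k < 0 || tree$height[k] < cut_level) {
        comps[[length(comps) + 1L]] <<- k
      } else {
        rec(tree$merge[k, 1])
        rec(tree$merge[k, 2])
      }
    }
    rec(k)
    comps
  }
  split_node <- function(k) {
    # k > 0: internal node index; k < 0: leaf
    if (k < 0) {
      candidates[[length(candidates) + 1L]] <<- -k
      return(invisible(NULL))
    }
    hs <- sort(tree$height[info$mergesets[[k]]])
    if (length(hs) >= 2L) {
      # multiplicative gaps, floored so near-zero heights cannot dominate
      lo <- pmax(hs[-length(hs)], 0.05 * hs[length(hs)])
      gaps <- hs[-1] / lo
      for (g in order(gaps, decreasing = TRUE)) {
        if (gaps[g] < ratio) break
        cut_level <- sqrt(hs[g + 1L] * max(hs[g], 1e-12))
        comps <- collect_components(k, cut_level)
        sizes <- vapply(comps, comp_size, integer(1))
        if (sum(sizes >= min_cluster_size) >= 2L) {
          for (comp in comps) split_node(comp)
          return(invisible(NULL))
        }
      }
    }
    candidates[[length(candidates) + 1L]] <<- info$leafsets[[k]]
  }
  if (n == 1L) {
    out <- stats::setNames(1L, labels)
  } else {
    split_node(nrow(tree$merge))
    sizes <- lengths(candidates)
    qualifying <- candidates[sizes >= min_cluster_size]
    if (!length(qualifying)) {
      lab <- if (fallback == "single") 1L else 0L
      out <- stats::setNames(rep.int(lab, n), labels)
    } else {
      assign <- integer(n)
      for (ci in seq_along(qualifying)) assign[qualifying[[ci]]] <- ci
      strays <- which(assign == 0L)
      if (length(strays) && pam_stage) {
        assert_that(!is.null(d), "PAM stage needs the distance matrix d")
        dm <- unclass(d)[labels, labels]
        for (i in strays) {
          avg <- vapply(qualifying, function(members) mean(dm[i, members]), numeric(1))
          assign[i] <- which.min(avg)  # ties -> lower cluster index
        }
      }
      # relabel clusters 1..k by first appearance in the dendrogram leaf order
      ord <- assign[tree$order]
      first <- ord[ord > 0L][!duplicated(ord[ord > 0L])]
      relab <- match(assign, first)
      relab[is.na(relab)] <- 0L
      out <- stats::setNames(as.integer(relab), labels)
    }
  }
  attr(out, "method") <- "dynamic_hybrid"
  attr(out, "params") <- list(min_cluster_size = as.integer(min_cluster_size),
                              deep_split = as.integer(deep_split),
                              ratio = ratio, pam_stage = pam_stage)
  out
}

# Within-cluster dispersion W_k = sum_r D_r / (2 n_r) with D_r the sum of
# squared pairwise distances inside cluster r (Tibshirani's pooled form).
within_dispersion <- function(dm, assign) {
  w <- 0
  for (cl in unique(assign)) {
    members <- which(assign == cl)
    if (length(members) > 1L) {
      sub <- dm[members, members]
      w <- w + sum(sub^2) / (2 * length(members))
    }
  }
  w
}

mean_silhouette <- function(dm, assign) {
  n <- length(assign)
  cls <- sort(unique(assign))
  if (length(cls) < 2L) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assign == assign[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(dm[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cls, assign[i]), function(cl) {
      mean(dm[i, assign == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Alternative tree-cut criteria: elbow, gap statistic, silhouette
#'
#' Partitions for each candidate k come from the complete-linkage tree via
#' [stats::cutree()]. The elbow criterion picks the k with maximum second
#' difference (curvature) of the within-cluster dispersion; the gap statistic
#' compares `log(W_k)` against B uniform reference draws over the data
#' bounding box and picks the smallest k with `Gap(k) >= Gap(k+1) - s(k+1)`;
#' the silhouette criterion maximises the mean silhouette width over
#' `k = 2..k_max`.
#'
#' @param d a `pn_distance_matrix`.
#' @param method one of `"elbow"`, `"gap"`, `"silhouette"`.
#' @param k_max largest k to consider (default `min(60, n - 1)`).
#' @param points n x 3 coordinate matrix (rows matching the matrix labels);
#'   required for `"gap"` to sample the uniform reference.
#' @param B number of gap-statistic reference draws (default 50).
#' @param seed RNG seed for the reference draws.
#' @return list with `k`, `assignment` (named integer vector), `method` and
#'   a `diagnostics` data frame of the criterion over k.
#' @export
cut_alternatives <- function(d, method = c("elbow", "gap", "silhouette"),
                             k_max = NULL, points = NULL, B = 50L, seed = NULL) {
  method <- match.arg(method)
  validate_distance_matrix(d)
  dm <- unclass(d)
  n <- nrow(dm)
  assert_that(n >= 3L, "need at least 3 neurons to choose a cluster number")
  k_max <- as.integer(k_max %||% min(60L, n - 1L))
  assert_that(k_max >= 2L && k_max <= n - 1L, "k_max must lie in 2..n-1")
  tree <- complete_linkage(d)
  cuts <- lapply(seq_len(k_max), function(k) stats::cutree(tree, k = k))

  if (method == "elbow") {
    w <- vapply(cuts, function(a) within_dispersion(dm, a), numeric(1))
    ks <- 2:(k_max - 1L)
    curv <- w[ks - 1L] - 2 * w[ks] + w[ks + 1L]
    k <- ks[which.max(curv)]
    diag_df <- data.frame(k = seq_len(k_max), W = w)
  } else if (method == "silhouette") {
    ks <- 2:k_max
    sil <- vapply(ks, function(k) mean_silhouette(dm, cuts[[k]]), numeric(1))
    k <- ks[which.max(sil)]
    diag_df <- data.frame(k = ks, silhouette = sil)
  } else { # gap
    assert_that(!is.null(points), "gap statistic needs the point coordinates")
    pts <- as.matrix(points)
    assert_that(nrow(pts) == n, "points must have one row per matrix label")
    if (!is.null(seed)) set.seed(seed)
    logw <- log(vapply(cuts, function(a) within_dispersion(dm, a), numeric(1)))
    ref <- matrix(NA_real_, B, k_max)
    lo <- apply(pts, 2L, min); hi <- apply(pts, 2L, max)
    for (b in seq_len(B)) {
      rp <- vapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]),
                   numeric(n))
      rdm <- as.matrix(stats::dist(rp))
      rtree <- stats::hclust(stats::as.dist(rdm), method = "complete")
      ref[b, ] <- log(vapply(seq_len(k_max), function(k) {
        within_dispersion(rdm, stats::cutree(rtree, k = k))
      }, numeric(1)))
    }
    gap <- colMeans(ref) - logw
    sk <- apply(ref, 2L, stats::sd) * sqrt(1 + 1 / B)
    k <- k_max
    for (kk in seq_len(k_max - 1L)) {
      if (gap[kk] >= gap[kk + 1L] - sk[kk + 1L]) { k <- kk; break }
    }
    diag_df <- data.frame(k = seq_len(k_max), gap = gap, se = sk)
  }
  assignment <- cuts[[k]]
  attr(assignment, "method") <- method
  list(k = k, assignment = assignment, method = method, diagnostics = diag_df)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths follow the merge heights (via [ape::as.phylo()]).
#'
#' @param tree an `hclust`.
#' @param path output path; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  assert_that(inherits(tree, "hclust"), "tree must be an hclust object")
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Export cluster assignments as delimited text
#'
#' @param assignment named vector from [cut_dynamic_hybrid()] or
#'   [cut_alternatives()]`$assignment`.
#' @param path output path (tab-separated).
#' @param neuropil optional neuropil tag column.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignment, path, neuropil = NA_character_) {
  df <- data.frame(neuron_id = names(assignment), neuropil = neuropil,
                   method = attr(assignment, "method") %||% NA_character_,
                   cluster = as.integer(assignment), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
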