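# The inter-PN distance and per-neuropil distance matrices.
#
# For two neurons with point sets A (the smaller, N_a points) and B, the
# distance is the root of the mean squared nearest-point distance:
#   d^2 = (1/N_a) * sum_i min_j || r_i - r_j ||^2.
# It is a proximity score, not a metric: the triangle inequality can fail, and
# downstream clustering must not assume metricity (it does not; complete
# linkage and the tree cut operate on the dissimilarities as given).

#' Inter-PN distance between two point sets
#'
#' Root-mean of squared nearest-point distances, taken from the smaller set to
#' the larger set. When both sets have the same size the first argument is the
#' reference set; the two orientations can then differ slightly, and
#' [distance_matrix()] resolves such ties deterministically.
#'
#' @param a,b n x 3 numeric matrices (or `skeleton` objects).
#' @return non-negative distance in micrometres.
#' @export
inter_pn_distance <- function(a, b) {
  a <- as_point_matrix(a, "a")
  b <- as_point_matrix(b, "b")
  if (nrow(a) > nrow(b)) { tmp <- a; a <- b; b <- tmp }
  sqrt(mean(nearest_sqdist(a, b)))
}

# Squared distance from each row of a to its nearest row of b, blockwise so
# the cross-distance matrix never exceeds ~4e6 doubles.
nearest_sqdist <- function(a, b) {
  bb <- rowSums(b * b)
  n <- nrow(a)
  chunk <- max(1L, floor(4e6 / nrow(b)))
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    ach <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(ach * ach), bb, `+`) - 2 * tcrossprod(ach, b)
    out[i:j] <- pmax(apply(d2, 1L, min), 0)
    i <- j + 1L
  }
  out
}

#' Pairwise inter-PN distance matrix within one neuropil
#'
#' Restricts each skeleton to its nodes inside the given neuropil and computes
#' all pairwise distances. Neurons with no node in the neuropil are excluded
#' with a warning. Rows/columns are ordered by sorted neuron id; equal-size
#' ties in the reference-set convention are resolved towards the
#' lexicographically smaller id, so the result is independent of input order.
#'
#' @param skeletons list of `skeleton` objects.
#' @param masks mask data frame from [build_masks()], or `NULL` to use all
#'   nodes of every skeleton.
#' @param neuropil neuropil tag to restrict to (ignored when `masks` is NULL).
#' @return a symmetric matrix of class `pn_distance_matrix` with zero diagonal
#'   and a `neuropil` attribute.
#' @export
distance_matrix <- function(skeletons, masks = NULL, neuropil = NULL) {
  ids <- vapply(skeletons, function(s) s$neuron_id, character(1))
  assert_that(!anyDuplicated(ids), "duplicate neuron ids among skeletons")
  pts <- list()
  for (s in skeletons) {
    p <- skeleton_points(s)
    if (!is.null(masks)) {
      assert_that(is.character(neuropil) && length(neuropil) == 1L,
                  "neuropil tag required when masks are supplied")
      sel <- masks$neuron_id == s$neuron_id & masks$neuropil == neuropil
      p <- p[s$nodes$node_id %in% masks$node_id[sel], , drop = FALSE]
    }
    if (nrow(p) == 0L) {
      warn_("neuron '%s' has no node in neuropil '%s'; excluded", s$neuron_id, neuropil %||% "")
      next
    }
    pts[[s$neuron_id]] <- p
  }
  assert_that(length(pts) >= 1L, "no neuron has nodes in the requested neuropil")
  ids <- sort(names(pts))
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        a <- pts[[ids[i]]]
        b <- pts[[ids[j]]]
        # tie on size: the lexicographically smaller id (row i) is the
        # reference set, which inter_pn_distance's first-argument rule gives us
        d <- inter_pn_distance(a, b)
        m[i, j] <- d
        m[j, i] <- d
      }
    }
  }
  structure(m, neuropil = neuropil %||% NA_character_, class = c("pn_distance_matrix", "matrix"))
}

validate_distance_matrix <- function(d, rel_tol = 1e-9) {
  m <- unclass(d)
  assert_that(is.matrix(m) && nrow(m) == ncol(m), "distance matrix must be square")
  assert_that(!is.null(rownames(m)) && identical(rownames(m), colnames(m)),
              "distance matrix must carry identical row/column neuron ids")
  assert_that(all(is.finite(m)) && all(m >= 0), "distances must be finite and non-negative")
  assert_that(all(diag(m) == 0), "distance matrix diagonal must be zero")
  asym <- max(abs(m - t(m)))
  scale <- max(abs(m), 1)
  assert_that(asym <= rel_tol * scale,
              "distance matrix is asymmetric beyond tolerance (max deviation %.3g)", asym)
  invisible(TRUE)
}

#' Export / import a distance matrix as labelled CSV
#'
#' Square CSV with the neuron ids as header row and first column. Import
#' validates symmetry within 1e-9 relative tolerance.
#'
#' @param d a `pn_distance_matrix`.
#' @param path file path.
#' @return `write_distance_matrix` returns `path` invisibly;
#'   `read_distance_matrix` the matrix.
#' @export
write_distance_matrix <- function(d, path) {
  validate_distance_matrix(d)
  df <- data.frame(neuron_id = rownames(d), unclass(d), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param neuropil neuropil tag to attach on import.
#' @export
read_distance_matrix <- function(path, neuropil = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  out <- structure(m, neuropil = neuropil, class = c("pn_distance_matrix", "matrix"))
  # symmetrize exactly after validation so downstream as.dist() is clean
  validate_distance_matrix(out)
  out[] <- (m + t(m)) / 2
  out
}
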