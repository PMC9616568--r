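# Categorical association between cluster labels and annotations:
# Pearson chi-square, bias-corrected Cramer's V, and plug-in mutual
# information with a permutation null.

#' Contingency table of two label vectors
#'
#' Counts of joint occurrences, with rows/columns in sorted label order
#' (deterministic).
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return integer matrix of counts with dimnames from the label levels.
#' @export
contingency <- function(labels_a, labels_b) {
  assert_that(length(labels_a) == length(labels_b),
              "label vectors differ in length (%d vs %d)",
              length(labels_a), length(labels_b))
  assert_that(length(labels_a) >= 1L, "label vectors are empty")
  a <- factor(as.character(labels_a))
  b <- factor(as.character(labels_b))
  tab <- table(a, b)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Pearson chi-square test of independence
#'
#' `chi2 = sum (O - E)^2 / E` with `E_ij = N p_i. p_.j`; the p-value is the
#' upper tail of the chi-square distribution with `(R - 1)(C - 1)` degrees of
#' freedom. No continuity correction is applied.
#'
#' @param tab contingency table (matrix of non-negative counts, R, C >= 2).
#' @return list with `chi2`, `dof`, `p`, `expected`, `N`, `R`, `C`.
#' @export
chi2_test <- function(tab) {
  m <- as.matrix(tab)
  assert_that(is.numeric(m) && all(m >= 0) && all(m == round(m)),
              "contingency table must hold non-negative integer counts")
  assert_that(nrow(m) >= 2L && ncol(m) >= 2L, "need at least a 2 x 2 table")
  N <- sum(m)
  assert_that(N > 0, "contingency table is empty")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0)) stop_("degenerate margin: all-zero row '%s'",
                          rownames(m)[which(rs == 0)[1]] %||% which(rs == 0)[1])
  if (any(cs == 0)) stop_("degenerate margin: all-zero column '%s'",
                          colnames(m)[which(cs == 0)[1]] %||% which(cs == 0)[1])
  expected <- outer(rs, cs) / N
  chi2 <- sum((m - expected)^2 / expected)
  dof <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(chi2 = chi2, dof = dof,
       p = stats::pchisq(chi2, df = dof, lower.tail = FALSE),
       expected = expected, N = N, R = nrow(m), C = ncol(m))
}

#' Bias-corrected Cramer's V
#'
#' `phi'^2 = max(0, chi2/N - (R-1)(C-1)/(N-1))`, `R' = R - (R-1)^2/(N-1)`,
#' `C' = C - (C-1)^2/(N-1)`, `V = sqrt(phi'^2 / min(R'-1, C'-1))`.
#'
#' @param chi2 Pearson chi-square statistic.
#' @param N total count (must exceed 1).
#' @param R,C numbers of rows and columns of the underlying table.
#' @return V in `[0, 1]`.
#' @export
cramers_v <- function(chi2, N, R, C) {
  assert_that(is.numeric(N) && N > 1, "N must exceed 1")
  phi2 <- max(0, chi2 / N - (R - 1) * (C - 1) / (N - 1))
  Rp <- R - (R - 1)^2 / (N - 1)
  Cp <- C - (C - 1)^2 / (N - 1)
  denom <- min(Rp - 1, Cp - 1)
  assert_that(denom > 0, "degenerate table: min(R'-1, C'-1) <= 0")
  sqrt(phi2 / denom)
}

# Fast plug-in MI (nats) on integer codes 1..na / 1..nb.
mi_from_codes <- function(ia, ib, na, nb) {
  N <- length(ia)
  joint <- tabulate((ia - 1L) * nb + ib, nbins = na * nb) / N
  pa <- tabulate(ia, nbins = na) / N
  pb <- tabulate(ib, nbins = nb) / N
  pp <- rep(pa, each = nb) * rep.int(pb, na)  # aligned with the joint layout
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / pp[nz]))
}

#' Plug-in mutual information between two labelings
#'
#' `I = sum_ij P(a_i, b_j) log [ P(a_i, b_j) / (P(a_i) P(b_j)) ]` in nats,
#' with empirical plug-in probabilities and the `0 log 0 = 0` convention.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return mutual information in nats (non-negative).
#' @export
mutual_information <- function(labels_a, labels_b) {
  assert_that(length(labels_a) == length(labels_b) && length(labels_a) >= 1L,
              "label vectors must be non-empty and of equal length")
  ia <- as.integer(factor(as.character(labels_a)))
  ib <- as.integer(factor(as.character(labels_b)))
  mi_from_codes(ia, ib, max(ia), max(ib))
}

#' Permutation p-value for the mutual information
#'
#' Permutes the second labeling uniformly `n_perm` times and reports
#' `p = (1 + #{I_perm >= I_obs}) / (n_perm + 1)` (the add-one correction keeps
#' p strictly positive). Significance is flagged at `alpha` (default 0.01).
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param n_perm number of permutations (at least 100; default 1000).
#' @param seed RNG seed.
#' @param alpha significance level for the `significant` flag.
#' @return list with `p`, `I_obs`, `significant`, `n_perm`.
#' @export
mi_permutation_p <- function(labels_a, labels_b, n_perm = 1000L, seed = NULL,
                             alpha = 0.01) {
  assert_that(is_count(n_perm, min = 100L), "n_perm must be an integer >= 100")
  assert_that(length(labels_a) == length(labels_b) && length(labels_a) >= 1L,
              "label vectors must be non-empty and of equal length")
  if (!is.null(seed)) set.seed(seed)
  ia <- as.integer(factor(as.character(labels_a)))
  ib <- as.integer(factor(as.character(labels_b)))
  na <- max(ia); nb <- max(ib)
  i_obs <- mi_from_codes(ia, ib, na, nb)
  n <- length(ia)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    i_perm <- mi_from_codes(ia, ib[sample.int(n)], na, nb)
    if (i_perm >= i_obs - 1e-12) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_perm + 1)
  list(p = p, I_obs = i_obs, significant = p < alpha, n_perm = n_perm)
}

#' Full association test between two labelings
#'
#' Bundles the contingency table, Pearson chi-square, bias-corrected Cramer's
#' V and the permutation-calibrated mutual information into one result.
#'
#' @inheritParams mi_permutation_p
#' @return list of class `association_result` with fields `table`, `chi2`,
#'   `dof`, `p_value`, `cramers_v`, `mi`, `mi_p`, `n_permutations`.
#' @export
association_test <- function(labels_a, labels_b, n_perm = 1000L, seed = NULL,
                             alpha = 0.01) {
  tab <- contingency(labels_a, labels_b)
  ct <- chi2_test(tab)
  v <- cramers_v(ct$chi2, ct$N, ct$R, ct$C)
  mi <- mi_permutation_p(labels_a, labels_b, n_perm = n_perm, seed = seed,
                         alpha = alpha)
  structure(list(table = tab, chi2 = ct$chi2, dof = ct$dof, p_value = ct$p,
                 cramers_v = v, mi = mi$I_obs, mi_p = mi$p,
                 n_permutations = n_perm),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("chi2 = %.4g (dof = %d, p = %.4g), Cramer's V = %.4g\n",
              x$chi2, x$dof, x$p_value, x$cramers_v))
  cat(sprintf("MI = %.4g nats (permutation p = %.4g, %d permutations)\n",
              x$mi, x$mi_p, x$n_permutations))
  invisible(x)
}

#' Read / write a contingency table with row and column headers
#'
#' @param tab integer matrix with dimnames.
#' @param path file path (CSV; first column holds the row labels).
#' @return `write_contingency` returns `path` invisibly; `read_contingency`
#'   the integer matrix.
#' @export
write_contingency <- function(tab, path) {
  df <- data.frame(label = rownames(tab), tab, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contingency
#' @export
read_contingency <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  m
}

#' The published valence-by-MB-cluster contingency table
#'
#' The packaged 3 x 10 table of putative valence (attractive / aversive /
#' unknown) against the ten MB-calyx spatial clusters of the 135 tri-neuropil
#' uPNs, shipped as a plain-text fixture. Note: this table as printed yields
#' chi2 = 62.57; see the package vignette for a discussion of the discrepancy
#' with the originally reported 66.1.
#'
#' @return integer matrix (3 rows, 10 columns).
#' @export
valence_mb_table <- function() {
  path <- system.file("extdata", "valence_mb_clusters.csv", package = "pnorg",
                      mustWork = TRUE)
  read_contingency(path)
}
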