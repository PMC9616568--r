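test_that("binarize_synapses applies the per-pair threshold and aggregates", {
  hmap <- c(u1 = "X", u2 = "X", u3 = "Y", u4 = "Y")
  tab <- data.frame(
    pre_id = c("u1", "u2", "u3", "u4", "u1"),
    post_id = c("p1", "p2", "p1", "p3", "p4"),
    weight = c(3L, 2L, 5L, 8L, 1L))
  C <- binarize_synapses(tab, threshold = 3, homotype_map = hmap)
  # hand binarization: X-p1 (w3 kept), X-p2 (w2 dropped), Y-p1, Y-p3; p4 dropped
  expect_equal(unclass(C)[, c("p1", "p3")],
               matrix(c(1L, 1L, 0L, 1L), 2, 2,
                      dimnames = list(c("X", "Y"), c("p1", "p3"))),
               ignore_attr = TRUE)
  expect_false("p2" %in% colnames(C))
  expect_false("p4" %in% colnames(C))

  # all weights below threshold: empty matrix, zero columns
  expect_equal(ncol(binarize_synapses(tab, threshold = 99, homotype_map = hmap)), 0L)

  expect_error(binarize_synapses(tab, threshold = 3, homotype_map = hmap[-1]),
               "without homotype")
  dup <- rbind(tab, tab[1, ])
  expect_error(binarize_synapses(dup, threshold = 1, homotype_map = hmap),
               "duplicate")
})

test_that("specificity and common synapses reproduce the schematic counts", {
  C <- fig9_matrix()
  sp <- specificity(C)
  expect_equal(sp$n_tot[sp$homotype == "A"], 3L)
  expect_equal(sp$n_sp[sp$homotype == "A"], 1L)
  expect_equal(sp$n_sp[sp$homotype == "D"], 2L)
  S <- common_synapses(C)
  expect_equal(S["B", "C"], 3L)
  expect_equal(unname(diag(S)), unname(rowSums(C)))

  # single homotype: everything is specific
  sp1 <- specificity(C[1, , drop = FALSE])
  expect_equal(sp1$n_sp, sp1$n_tot)

  # random matrices: brute-force column scan and C %*% t(C) oracles
  set.seed(27)
  for (rep in 1:5) {
    M <- matrix(rbinom(100, 1, 0.4), 5, 20,
                dimnames = list(paste0("h", 1:5), paste0("p", 1:20)))
    spm <- specificity(M)
    for (x in 1:5) {
      nsp <- 0L
      for (i in 1:20) if (M[x, i] == 1 && sum(M[, i]) == 1) nsp <- nsp + 1L
      expect_equal(spm$n_sp[x], nsp)
      expect_equal(spm$n_tot[x], sum(M[x, ]))
    }
    expect_equal(unclass(common_synapses(M)), M %*% t(M))
    # sum of specific counts can never exceed the partner count
    expect_lte(sum(spm$n_sp), ncol(M))
  }
})

test_that("cosine distance matches hand arithmetic", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0, 1), c(0, 1, 0)), 1)
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 0, 0)), 1 - 1 / sqrt(2))
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero vector")
})

test_that("connectivity clustering is Ward on cosine distances", {
  # identical rows merge at height 0
  M <- rbind(a = c(1L, 1L, 0L, 0L), b = c(1L, 1L, 0L, 0L),
             c = c(0L, 0L, 1L, 1L), d = c(0L, 1L, 1L, 1L))
  tree <- connectivity_clustering(M)
  expect_equal(min(tree$height), 0)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))

  # hand Lance-Williams Ward oracle on the same 4 rows
  ward_oracle <- function(D) {
    sizes <- rep(1, nrow(D)); active <- seq_len(nrow(D)); heights <- c()
    while (length(active) > 1) {
      best <- c(Inf, NA, NA)
      for (ii in seq_along(active)) for (jj in seq_along(active)) {
        if (ii < jj && D[active[ii], active[jj]] < best[1]) {
          best <- c(D[active[ii], active[jj]], active[ii], active[jj])
        }
      }
      i <- best[2]; j <- best[3]
      heights <- c(heights, best[1])
      for (k in setdiff(active, c(i, j))) {
        ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
        upd <- sqrt(((ni + nk) * D[i, k]^2 + (nj + nk) * D[j, k]^2 -
                       nk * D[i, j]^2) / (ni + nj + nk))
        D[i, k] <- D[k, i] <- upd
      }
      sizes[i] <- sizes[i] + sizes[j]
      active <- setdiff(active, j)
    }
    heights
  }
  D0 <- outer(seq_len(nrow(M)), seq_len(nrow(M)),
              Vectorize(function(i, j) if (i == j) 0 else cosine_distance(M[i, ], M[j, ])))
  expect_equal(tree$height, ward_oracle(D0), tolerance = 1e-12)

  # zero rows are excluded with a warning
  M0 <- rbind(M, e = c(0L, 0L, 0L, 0L))
  expect_warning(tree0 <- connectivity_clustering(M0), "no retained")
  expect_setequal(tree0$labels, rownames(M))

  # homotypic uPNs (similar planted rows) merge before heterotypic ones
  pop_map <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  syn <- generate_synapses(connectivity_spec(c("A", "B"), c(8, 8), c(1, 1)),
                           seed = 4, upn_map = pop_map, member_p = 1)
  Cu <- binarize_synapses(syn$table, threshold = 1, homotype_map = pop_map,
                          level = "upn")
  tr <- connectivity_clustering(Cu)
  first_two <- sort(-tr$merge[1:2, ])
  expect_setequal(substr(tr$labels[first_two], 1, 1), c("a", "a", "b", "b"))
})

test_that("tanglegram statistics behave at their fixed points", {
  set.seed(33)
  d <- dist_matrix_of(random_points(10, sd = 4))
  t1 <- complete_linkage(d)
  ts <- tanglegram_stats(t1, t1)
  expect_equal(ts$bakers_gamma, 1)
  expect_equal(ts$entanglement, 0)
  expect_equal(ts$cophenetic_r, 1)

  # same topology, fully reversed leaf order: untangling recovers order 0
  t2 <- t1
  t2$order <- rev(t1$order)
  expect_equal(tanglegram_stats(t1, t2)$entanglement, 0)

  # independent random trees: gamma near zero on average
  gammas <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    ta <- complete_linkage(dist_matrix_of(random_points(8, sd = 3)))
    tb <- complete_linkage(dist_matrix_of(random_points(8, sd = 3)))
    tanglegram_stats(ta, tb, untangle = FALSE)$bakers_gamma
  }, numeric(1))
  expect_lt(abs(mean(gammas)), 0.2)

  t3 <- complete_linkage(dist_matrix_of(random_points(9, sd = 3)))
  expect_error(tanglegram_stats(t1, t3), "identical leaf set")

  # congruent trees beat the permutation null
  pn <- tanglegram_null(t1, t1, stat = "cophenetic_r", n_perm = 99, seed = 2)
  expect_equal(pn$p, 0.01)
})

test_that("raising the threshold never increases N_tot or S", {
  set.seed(41)
  pop_map <- stats::setNames(rep(paste0("H", 1:6), each = 3),
                             paste0("u", 1:18))
  syn <- generate_synapses(
    connectivity_spec(paste0("H", 1:6), rep(10L, 6), rep(0.3, 6)),
    seed = 8, upn_map = pop_map, weight_mean = 6)
  C3 <- binarize_synapses(syn$table, threshold = 3, homotype_map = pop_map)
  C8 <- binarize_synapses(syn$table, threshold = 8, homotype_map = pop_map)
  s3 <- specificity(C3); s8 <- specificity(C8)
  n8 <- stats::setNames(s8$n_tot, s8$homotype)[s3$homotype]
  n8[is.na(n8)] <- 0L
  expect_true(all(n8 <= s3$n_tot))
  S3 <- common_synapses(C3); S8 <- common_synapses(C8)
  common <- intersect(rownames(S3), rownames(S8))
  expect_true(all(S8[common, common] <= S3[common, common]))
})

test_that("synapse tables round-trip through delimited text", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(pre_id = c("u1", "u2"), post_id = c("p1", "p1"),
                   interface = "PN-KC", weight = c(4L, 2L))
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_synapse_table(f)
  expect_equal(back$weight, df$weight)
  expect_equal(back$pre_id, df$pre_id)
})
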