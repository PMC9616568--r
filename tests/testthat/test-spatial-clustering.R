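test_that("complete linkage follows the farthest-point rule", {
  # 2 leaves: one merge at their distance
  d2 <- dist_matrix_of(rbind(c(0, 0, 0), c(3, 0, 0)), ids = c("a", "b"))
  t2 <- complete_linkage(d2)
  expect_equal(t2$height, 3)

  # 3 leaves, d12 = 1, d13 = 5, d23 = 6: merge {1,2}@1 then all @6 (max rule)
  m <- matrix(c(0, 1, 5, 1, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d3 <- structure(m, class = c("pn_distance_matrix", "matrix"))
  t3 <- complete_linkage(d3)
  expect_equal(t3$height, c(1, 6))
  expect_equal(t3$merge[1, ], c(-1, -2))

  # ultrametric input: the dendrogram reproduces the ultrametric exactly
  set.seed(5)
  base <- complete_linkage(dist_matrix_of(random_points(8)))
  um <- as.matrix(cophenetic(base))
  du <- structure(um, class = c("pn_distance_matrix", "matrix"))
  expect_equal(as.matrix(cophenetic(complete_linkage(du)))[rownames(um), colnames(um)],
               um, tolerance = 1e-12)

  m_bad <- m; m_bad[1, 2] <- 2
  expect_error(complete_linkage(structure(m_bad, class = c("pn_distance_matrix", "matrix"))),
               "asymmetric")
})

test_that("dynamic hybrid cut separates bundles and respects the minimum size", {
  set.seed(21)
  # two bundles of 6 with separation >> spread: exactly the two bundles
  pts <- rbind(blob3(6, c(0, 0, 0), 0.5), blob3(6, c(50, 0, 0), 0.5))
  d <- dist_matrix_of(pts)
  cut <- cut_dynamic_hybrid(complete_linkage(d), d, min_cluster_size = 4)
  expect_equal(length(unique(cut)), 2L)
  expect_equal(as.vector(cut), rep(as.vector(cut)[c(1, 7)], each = 6))

  # a single tight bundle stays whole
  d1 <- dist_matrix_of(blob3(10, c(0, 0, 0), 0.5))
  cut1 <- cut_dynamic_hybrid(complete_linkage(d1), d1)
  expect_equal(as.vector(cut1), rep(1L, 10))

  # n below the minimum size: fallback behaviour is configurable
  dsmall <- dist_matrix_of(blob3(3, c(0, 0, 0), 0.5))
  tsmall <- complete_linkage(dsmall)
  expect_equal(as.vector(cut_dynamic_hybrid(tsmall, dsmall, min_cluster_size = 4)),
               rep(1L, 3))
  expect_equal(as.vector(cut_dynamic_hybrid(tsmall, dsmall, min_cluster_size = 4,
                                            fallback = "unassigned")),
               rep(0L, 3))

  # with min size 1 and clean separation: the components-at-gap partition
  pts3 <- rbind(blob3(4, c(0, 0, 0), 0.3), blob3(4, c(40, 0, 0), 0.3),
                blob3(4, c(80, 40, 0), 0.3))
  d3 <- dist_matrix_of(pts3)
  cut3 <- cut_dynamic_hybrid(complete_linkage(d3), d3, min_cluster_size = 1)
  expect_equal(as.vector(cut3), rep(as.vector(cut3)[c(1, 5, 9)], each = 4))

  # assignments are invariant under leaf relabeling / matrix permutation
  perm <- sample(nrow(d3))
  dp <- structure(unclass(d3)[perm, perm], class = class(d3))
  cutp <- cut_dynamic_hybrid(complete_linkage(dp), dp, min_cluster_size = 1)
  expect_equal(ari(cut3[rownames(dp)], cutp), 1)
})

test_that("hybrid cut recovers planted bundles on generator scenes", {
  ok <- 0L
  for (seed in 1:5) {
    pop <- generate_population(
      bundle_spec(c("DA1", "DL5", "VA2", "DM1", "VC1", "DM2"),
                  n_neurons = rep(5L, 6), sigma = 1),
      seed = seed, anchor_spread = c(20, 20, 20), backbone = FALSE)
    d <- distance_matrix(pop$skeletons)
    cut <- cut_dynamic_hybrid(complete_linkage(d), d, min_cluster_size = 4)
    truth <- pop$annotations$homotype[match(names(cut), pop$annotations$neuron_id)]
    if (ari(cut, truth) >= 0.95) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("alternative criteria pick the constructed k", {
  set.seed(23)
  pts3 <- rbind(blob3(10, c(0, 0, 0)), blob3(10, c(10, 0, 0)), blob3(10, c(0, 20, 0)))
  d3 <- dist_matrix_of(pts3)
  expect_equal(cut_alternatives(d3, "silhouette", k_max = 10)$k, 3L)

  pts2 <- rbind(blob3(10, c(0, 0, 0)), blob3(10, c(10, 0, 0)))
  d2 <- dist_matrix_of(pts2)
  expect_equal(cut_alternatives(d2, "elbow", k_max = 8)$k, 2L)

  # gap statistic favours k = 1 on a single uniform blob (seeded)
  set.seed(55)
  pu <- matrix(runif(90, 0, 10), ncol = 3)
  du <- dist_matrix_of(pu)
  expect_equal(cut_alternatives(du, "gap", k_max = 6, points = pu, seed = 5)$k, 1L)
  expect_equal(cut_alternatives(d3, "gap", k_max = 8, points = pts3, seed = 5)$k, 3L)

  expect_error(cut_alternatives(d3, "gap", k_max = 5), "point coordinates")
})

test_that("dendrograms export to Newick with merge heights", {
  d <- dist_matrix_of(rbind(c(0, 0, 0), c(3, 0, 0), c(10, 0, 0)),
                      ids = c("a", "b", "c"))
  nwk <- dendrogram_newick(complete_linkage(d))
  expect_match(nwk, "^\\(")
  expect_true(all(vapply(c("a", "b", "c"), grepl, logical(1), x = nwk)))
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
})
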