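test_that("density profiles conserve counts and respect rotations", {
  set.seed(1)
  pts <- cbind(runif(400, 0, 10), rnorm(400), rnorm(400))
  prof <- density_profile(pts, rotation = c(0, 0, 0), axis = 1, bin_width = 1)
  expect_equal(sum(prof$density), 400)
  # roughly flat: occupied interior bins stay near the uniform expectation
  interior <- prof$density[prof$mids > 1 & prof$mids < 9]
  expect_true(all(interior > 0.3 * mean(interior)))

  # identity rotation leaves the profile unchanged; point order irrelevant
  prof0 <- density_profile(pts[sample.int(400), ], axis = 1, bin_width = 1)
  expect_equal(prof0$density, prof$density)

  # two separated blobs give an interior minimum between the modes
  set.seed(2)
  blobs <- rbind(blob3(150, c(0, 0, 0), 2), blob3(150, c(30, 0, 0), 2))
  pm <- profile_minima(density_profile(blobs, axis = 1, bin_width = 2))
  expect_gt(nrow(pm), 0)
  expect_true(any(pm$position > 5 & pm$position < 25))

  # rotating 90 degrees about z maps x-separation into y-separation
  prof_y <- density_profile(blobs, rotation = c(0, 0, 90), axis = 2, bin_width = 2)
  expect_gt(nrow(profile_minima(prof_y)), 0)

  expect_error(density_profile(matrix(1, 5, 3), axis = 1), "degenerate")
})

test_that("scan_rotations finds separating rotations or signals inseparable", {
  set.seed(3)
  # blobs separated along the 45-degree direction in the x-y plane, with a
  # spread large enough that only near-aligned projections separate them
  u <- c(cos(pi / 4), sin(pi / 4), 0)
  blobs <- rbind(blob3(1500, -15 * u, 8), blob3(1500, 15 * u, 8))
  res <- scan_rotations(blobs, axis = 1, increment = 15)
  expect_true(res$separable)
  # x' = t cos(theta + 45): alignment at theta = 135 or 315 about z
  expect_equal(res$rotation_axis, 3L)
  expect_lte(min(abs(res$angle - 135), abs(res$angle - 315)), 15)

  # a single blob has no qualifying interior minimum
  single <- blob3(300, c(0, 0, 0), 2)
  expect_false(scan_rotations(single, axis = 1, increment = 30)$separable)

  # coarse grid on axis-aligned blobs picks the identity
  axial <- rbind(blob3(200, c(-15, 0, 0), 1.5), blob3(200, c(15, 0, 0), 1.5))
  res90 <- scan_rotations(axial, axis = 1, increment = 90)
  expect_equal(res90$rotation, c(0, 0, 0))
})

test_that("build_masks applies conjunctive half-open rules", {
  s <- skeleton("t", data.frame(node_id = 1:3, structure = 0L,
                                x = c(0, 1, 0.5), y = 0, z = 0, radius = 1,
                                parent_id = c(-1L, 1L, 1L)))
  rule <- segmentation_rule("AL", list(list(rotation = c(0, 0, 0), axis = 1,
                                            interval = c(0, 1))))
  masks <- build_masks(list(rule), list(s))
  # lower-closed: x = 0 in, x = 1 out
  expect_equal(sort(masks$node_id), c(1L, 3L))

  # empty rule set: nothing assigned
  expect_equal(nrow(build_masks(list(), list(s))), 0L)

  # overlapping rules are an error naming both neuropils
  rule2 <- segmentation_rule("LH", list(list(rotation = c(0, 0, 0), axis = 1,
                                             interval = c(-1, 2))))
  expect_error(build_masks(list(rule, rule2), list(s)), "overlapping rules")

  # translation applied to points and intervals together is a no-op
  s2 <- s
  s2$nodes$x <- s$nodes$x + 100
  rule_t <- segmentation_rule("AL", list(list(rotation = c(0, 0, 0), axis = 1,
                                              interval = c(100, 101))))
  expect_equal(build_masks(list(rule_t), list(s2))$node_id, masks$node_id)
})

test_that("segment_scene recovers planted region membership", {
  # arbor-only scene: exact recovery; with backbones: region nodes still exact
  for (backbone in c(FALSE, TRUE)) {
    pop <- toy_population(seed = 7, backbone = backbone)
    seg <- segment_scene(pop$skeletons)
    merged <- merge(pop$ground_truth, seg$masks,
                    by = c("neuron_id", "node_id"), all.x = TRUE)
    region_nodes <- merged[merged$region %in% c("AL", "MB_calyx", "LH"), ]
    expect_equal(region_nodes$neuropil, region_nodes$region,
                 label = sprintf("backbone=%s masks", backbone))
    if (!backbone) {
      # nothing but region nodes exists, so the masks match the truth exactly
      expect_equal(nrow(seg$masks), nrow(region_nodes))
    }
  }
})
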