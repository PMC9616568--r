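test_that("read_swc parses, scales and validates", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines("1 1 0 0 0 1 -1", f)
  s <- read_swc(f, unit_scale = 1)
  expect_s3_class(s, "skeleton")
  expect_equal(nrow(s$nodes), 1L)
  expect_equal(unname(skeleton_points(s)[1, ]), c(0, 0, 0))

  # nanometre-style raw file with scale 0.001
  writeLines(c("# comment", "1 1 1000 2000 -500 40 -1"), f)
  s <- read_swc(f, unit_scale = 0.001)
  expect_equal(unname(skeleton_points(s)[1, ]), c(1, 2, -0.5))
  expect_equal(s$nodes$radius, 0.04)

  # malformed line reported with its line number
  writeLines(c("1 1 0 0 0 1 -1", "2 1 0 0 0 1"), f)
  expect_error(read_swc(f), "line 2")
  writeLines(c("1 1 0 0 0 1 -1", "2 1 zero 0 0 1 1"), f)
  expect_error(read_swc(f), "line 2")
  # dangling parent
  writeLines(c("1 1 0 0 0 1 -1", "2 1 1 0 0 1 99"), f)
  expect_error(read_swc(f), "missing parent 99")
  # empty file
  writeLines("# only comments", f)
  expect_error(read_swc(f), "no data lines")
})

test_that("write_swc round-trips skeletons exactly enough", {
  f <- withr::local_tempfile(fileext = ".swc")
  # 3-node chain
  chain <- skeleton("c", data.frame(node_id = 1:3, structure = c(1L, 0L, 0L),
                                    x = c(0, 1.5, 3.25), y = c(0, -2, 4),
                                    z = c(0, 0.1, 0.2), radius = c(1, 0.5, 0.25),
                                    parent_id = c(-1L, 1L, 2L)))
  write_swc(chain, f)
  back <- read_swc(f, neuron_id = "c")
  expect_equal(back$nodes, chain$nodes)

  # property: random trees round-trip node-for-node
  set.seed(101)
  for (rep in 1:5) {
    s <- random_skeleton(100, "p")
    write_swc(s, f)
    expect_equal(read_swc(f, neuron_id = "p")$nodes, s$nodes, tolerance = 1e-12)
  }

  # degenerate: refuse empty skeletons
  empty <- chain
  empty$nodes <- chain$nodes[0, ]
  expect_error(write_swc(empty, f), "empty")
})

test_that("skeleton constructor enforces the tree invariants", {
  nodes <- data.frame(node_id = c(1L, 1L), structure = 0L, x = 0, y = 0, z = 0,
                      radius = 1, parent_id = c(-1L, 1L))
  expect_error(skeleton("dup", nodes), "duplicate node_id")
  nodes <- data.frame(node_id = 1:2, structure = 0L, x = 0, y = 0, z = 0,
                      radius = 1, parent_id = c(2L, 1L))
  expect_error(skeleton("cyc", nodes), "no root")
  # fragmented file accepted as a forest, with a warning
  nodes <- data.frame(node_id = 1:2, structure = 0L, x = 0:1, y = 0, z = 0,
                      radius = 1, parent_id = c(-1L, -1L))
  expect_warning(s <- skeleton("frag", nodes), "fragmented")
  expect_equal(nrow(s$nodes), 2L)
})

test_that("annotations validate vocabularies and apply the alias map", {
  df <- data.frame(neuron_id = c("a", "b", "c"),
                   homotype = c("VC3l", "VC5", "DA1"),
                   odor_type = c("fruity", "pheromones", "hygro/thermo"),
                   valence = c("attractive", "aversive", "unknown"),
                   tract = c("mALT", "mlALT", "unknown"))
  tab <- neuron_table(df)
  # simultaneous renaming: VC3l -> VC3 and VC5 -> VM6 (no cascade)
  expect_equal(tab$homotype, c("VC3", "VM6", "DA1"))
  expect_equal(neuron_table(df, alias_map = NULL)$homotype, df$homotype)
  df$valence[1] <- "meh"
  expect_error(neuron_table(df), "unknown valence")
})

test_that("packaged valence fixture carries 17 attractive and 25 aversive homotypes", {
  hv <- homotype_valences()
  expect_equal(sum(hv$valence == "attractive"), 17L)
  expect_equal(sum(hv$valence == "aversive"), 25L)
  expect_false(anyDuplicated(hv$homotype) > 0)
})

test_that("select_upns keeps exactly the tri-neuropil neurons", {
  ann <- neuron_table(data.frame(
    neuron_id = paste0("n", 1:7), homotype = "DA1", odor_type = "fruity",
    valence = "attractive", tract = "mALT"))
  mask_for <- function(id, neuropils) {
    data.frame(neuron_id = id, node_id = seq_along(neuropils), neuropil = neuropils)
  }
  masks <- rbind(
    do.call(rbind, lapply(paste0("n", 1:5), mask_for,
                          neuropils = c("AL", "MB_calyx", "LH"))),
    mask_for("n6", c("AL", "MB_calyx")),
    mask_for("n7", c("AL", "LH")))
  expect_equal(select_upns(ann, masks), paste0("n", 1:5))
  # idempotent and independent of row order
  shuffled <- masks[sample.int(nrow(masks)), ]
  expect_equal(select_upns(ann, shuffled), select_upns(ann, masks))
  # unknown neuron excluded with a warning
  masks2 <- rbind(masks, mask_for("ghost", c("AL", "MB_calyx", "LH")))
  expect_warning(sel <- select_upns(ann, masks2), "ghost")
  expect_equal(sel, paste0("n", 1:5))
})
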