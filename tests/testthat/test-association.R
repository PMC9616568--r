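test_that("contingency counts joint occurrences deterministically", {
  tab <- contingency(c("A", "A", "B"), c("x", "y", "x"))
  expect_equal(unclass(tab), matrix(c(1L, 1L, 1L, 0L), 2, 2,
                                    dimnames = list(c("A", "B"), c("x", "y"))))
  # identical vectors produce a diagonal table
  v <- rep(c("a", "b", "c"), times = c(2, 3, 4))
  expect_equal(unname(diag(contingency(v, v))), c(2L, 3L, 4L))
  expect_equal(sum(contingency(v, v)) , 9L)
  expect_error(contingency(1:3, 1:4), "length")
})

test_that("chi2_test follows the closed forms and invariances", {
  # table proportional to the outer product of its margins: chi2 = 0, p = 1
  indep <- outer(c(2L, 4L), c(3L, 6L, 9L))
  res <- chi2_test(indep)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)

  # 2x2 closed form N (ad - bc)^2 / (r1 r2 c1 c2)
  res2 <- chi2_test(rbind(c(10, 0), c(0, 10)))
  expect_equal(res2$chi2, 20 * (10 * 10)^2 / (10 * 10 * 10 * 10))
  expect_equal(res2$dof, 1L)

  # row/column permutation invariance; integer count scaling scales chi2
  set.seed(9)
  tab <- matrix(rpois(12, 8) + 1L, 3, 4)
  base <- chi2_test(tab)$chi2
  expect_equal(chi2_test(tab[c(2, 3, 1), c(4, 1, 3, 2)])$chi2, base)
  expect_equal(chi2_test(tab * 5L)$chi2, 5 * base)

  expect_error(chi2_test(rbind(c(0, 0), c(1, 2))), "all-zero row")
  expect_error(chi2_test(rbind(c(1, 0), c(2, 0))), "all-zero column")
})

test_that("bias-corrected Cramer's V matches direct formula evaluation", {
  expect_equal(cramers_v(0, 100, 3, 4), 0)

  # 2x2 perfect association: phi'^2 = 18/19 and min(R'-1, C'-1) = 18/19
  expect_equal(cramers_v(20, 20, 2, 2), 1)

  # direct evaluation on the reported worked-example inputs
  chi2 <- 66.1; N <- 135; R <- 3; C <- 10
  phi2 <- max(0, chi2 / N - (R - 1) * (C - 1) / (N - 1))
  vref <- sqrt(phi2 / min(R - (R - 1)^2 / (N - 1) - 1, C - (C - 1)^2 / (N - 1) - 1))
  expect_equal(cramers_v(chi2, N, R, C), vref)
  expect_equal(round(cramers_v(chi2, N, R, C), 3), 0.425)

  expect_error(cramers_v(5, 2, 3, 3), "degenerate")
})

test_that("mutual information follows the plug-in formula", {
  expect_equal(mutual_information(rep("k", 6), c("a", "b", "a", "b", "a", "b")), 0)
  expect_equal(mutual_information(rep(c("a", "b"), 5), rep(c("x", "y"), 5)), log(2))

  # joint counts [[2,0],[0,1],[0,1]], N = 4:
  # I = .5 ln(.5/.25) + .25 ln(.25/.125) + .25 ln(.25/.125) = ln 2
  a <- c("r1", "r1", "r2", "r3")
  b <- c("c1", "c1", "c2", "c2")
  expect_equal(mutual_information(a, b), log(2))

  # symmetry and the entropy bound
  set.seed(17)
  for (rep in 1:10) {
    x <- sample(letters[1:4], 40, replace = TRUE)
    y <- sample(LETTERS[1:3], 40, replace = TRUE)
    i <- mutual_information(x, y)
    expect_gte(i, 0)
    expect_equal(i, mutual_information(y, x))
    expect_lte(i, min(log(length(unique(x))), log(length(unique(y)))) + 1e-12)
  }
})

test_that("mi_permutation_p attains its bounds", {
  v <- rep(letters[1:3], each = 10)
  r <- mi_permutation_p(v, v, n_perm = 999, seed = 3)
  expect_equal(r$p, 1 / 1000)   # minimum attainable with the +1 correction
  expect_true(r$significant)

  rc <- mi_permutation_p(rep("k", 30), v, n_perm = 200, seed = 3)
  expect_equal(rc$I_obs, 0)
  expect_equal(rc$p, 1)
  expect_error(mi_permutation_p(v, v, n_perm = 50), "100")
})

test_that("association_test bundles the statistics coherently", {
  set.seed(19)
  a <- rep(c("u", "v", "w"), each = 12)
  b <- ifelse(runif(36) < 0.8, a, sample(c("u", "v", "w"), 36, replace = TRUE))
  res <- association_test(a, b, n_perm = 500, seed = 7)
  expect_equal(res$dof, 4L)
  expect_equal(res$chi2, chi2_test(contingency(a, b))$chi2)
  expect_equal(res$cramers_v, cramers_v(res$chi2, 36, 3, 3))
  expect_lt(res$mi_p, 0.05)
})

test_that("contingency tables round-trip through CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- valence_mb_table()
  write_contingency(tab, f)
  expect_equal(read_contingency(f), tab)
  expect_equal(dim(tab), c(3L, 10L))
  expect_equal(sum(tab), 135L)
})
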