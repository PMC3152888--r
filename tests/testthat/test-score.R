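test_that("raw score is the negative sum of log p-values", {
  b_all1 <- bicluster(c("a", "b"), "s1", pvalues = c(1, 1))
  expect_equal(bicluster_score(b_all1), 0)
  b <- bicluster(c("a", "b"), "s1", pvalues = c(0.1, 0.01))
  expect_equal(bicluster_score(b), -(log(0.1) + log(0.01)))
  expect_equal(bicluster_score(b), 6.907755, tolerance = 1e-6)
  # appending a gene with p < 1 strictly increases the score
  b3 <- bicluster(c("a", "b", "c"), "s1", pvalues = c(0.1, 0.01, 0.5))
  expect_gt(bicluster_score(b3), bicluster_score(b))
  expect_error(bicluster_score(bicluster("a", "s1")), "p-values")
})

test_that("expected_score is deterministic under a seed and 0 when degenerate", {
  B <- make_three_block_binary()
  attr(B, "direction") <- "up"
  b <- bicluster(c("g1", "g2"), sprintf("s%d", 1:10), direction = "up",
                 pvalues = c(0.001, 0.001))
  e1 <- expected_score(b, B, n_random = 200, seed = 42)
  e2 <- expected_score(b, B, n_random = 200, seed = 42)
  expect_identical(e1, e2)
  expect_gt(e1, 0)
  # all-ones gene rows give p = 1 against any phenotype: expected score 0
  Bones <- matrix(1L, 3, 10,
                  dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:10)))
  attr(Bones, "direction") <- "up"
  bo <- bicluster(c("g1", "g2"), sprintf("s%d", 1:4), direction = "up",
                  pvalues = c(1, 1))
  expect_equal(expected_score(bo, Bones, n_random = 50, seed = 1), 0)
})

test_that("total score sums normalized scores and is order-invariant", {
  expect_equal(total_score(bicluster_set()), 0)
  b1 <- bicluster("a", "s1", pvalues = 0.5, score = 1, nscore = 3.2)
  b2 <- bicluster("b", "s2", pvalues = 0.5, score = 1, nscore = 0.8)
  expect_equal(total_score(bicluster_set(list(b1))), 3.2)
  expect_equal(total_score(bicluster_set(list(b1, b2))),
               total_score(bicluster_set(list(b2, b1))))
})

test_that("a planted block scores far above its randomization null", {
  sc <- generate_scenario(n_genes = 60, n_samples = 30, n_biclusters = 3,
                          bic_rows = 10, bic_cols = 5, seed = 8)
  res <- debi(sc$exprs, alpha = 0.001, n_random = 300, seed = 8, L = 0.5)
  expect_gte(length(res), 3L)
  ni <- vapply(unclass(res), `[[`, numeric(1), "nscore")
  expect_true(all(ni > 5))
})

test_that("null-matrix biclusters have normalized scores near 1", {
  # fixed-position biclusters in an i.i.d. Bernoulli matrix: the observed
  # p-values follow the same law as the randomization draws, so NI ~ 1
  withr::local_seed(19)
  B <- random_binary(60, 30, 0.2)
  rownames(B) <- sprintf("g%d", 1:60)
  colnames(B) <- sprintf("s%d", 1:30)
  attr(B, "direction") <- "as_given"
  ni <- vapply(1:12, function(k) {
    genes <- sprintf("g%d", ((k - 1) * 5 + 1):(k * 5))
    samples <- sample(colnames(B), 6)
    pv <- vapply(genes, function(g) {
      fisher_association(B[g, ], colnames(B) %in% samples)
    }, numeric(1))
    b <- bicluster(genes, samples, direction = "as_given", pvalues = pv)
    iv <- bicluster_score(b)
    ev <- expected_score(b, B, n_random = 300)
    if (ev > 0) iv / ev else 0
  }, numeric(1))
  expect_gt(mean(ni), 0.5)
  expect_lt(mean(ni), 2)
})

test_that("select_alpha honors the grid, ties, and reproducibility", {
  sc <- generate_scenario(n_genes = 50, n_samples = 25, n_biclusters = 5,
                          bic_rows = 10, bic_cols = 5, seed = 4)
  # grid of length 1 returns that alpha
  one <- select_alpha(sc$exprs, grid = 0.01, n_random = 100, seed = 4)
  expect_equal(one$alpha, 0.01)
  # result is invariant to grid order and reproducible end-to-end
  g <- c(1e-2, 1e-4, 1e-8)
  a <- select_alpha(sc$exprs, grid = g, n_random = 100, seed = 4)
  b <- select_alpha(sc$exprs, grid = rev(g), n_random = 100, seed = 4)
  expect_equal(a$alpha, b$alpha)
  expect_equal(a$cs_table$cs, b$cs_table$cs[match(a$cs_table$alpha,
                                                  b$cs_table$alpha)])
  c2 <- select_alpha(sc$exprs, grid = g, n_random = 100, seed = 4)
  expect_equal(a$cs_table, c2$cs_table)
  expect_gt(attr(a$result, "cs"), 0)
})

test_that("identical configuration and seed give byte-identical outputs", {
  sc <- generate_scenario(n_genes = 50, n_samples = 25, n_biclusters = 5,
                          bic_rows = 10, bic_cols = 5, noise = 0.05, seed = 21)
  f1 <- withr::local_tempfile(fileext = ".txt")
  f2 <- withr::local_tempfile(fileext = ".txt")
  r1 <- debi(sc$exprs, alpha = "select", grid = c(1e-2, 1e-4),
             n_random = 100, seed = 21)
  r2 <- debi(sc$exprs, alpha = "select", grid = c(1e-2, 1e-4),
             n_random = 100, seed = 21)
  write_biclusters(r1, f1)
  write_biclusters(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(attr(r1, "cs_table"), attr(r2, "cs_table"))
})
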