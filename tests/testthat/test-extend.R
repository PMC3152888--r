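test_that("fisher_association matches hand-derived exact values", {
  v <- c(1, 1, 1, 1, 0, 0, 0, 0)
  # perfect agreement: only 1 of the choose(8,4) placements is this extreme
  expect_equal(fisher_association(v, v), 1 / choose(8, 4), tolerance = 1e-15)
  # an all-ones gene carries no information
  expect_equal(fisher_association(rep(1, 8), v), 1)
  # perfect depletion is the far end of the one-sided upper tail
  expect_equal(fisher_association(1 - v, v), 1)
  # degenerate phenotype vectors give p = 1 by convention
  expect_equal(fisher_association(v, rep(1, 8)), 1)
  expect_equal(fisher_association(v, rep(0, 8)), 1)
  expect_error(fisher_association(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("fisher_association equals the enumeration oracle on random pairs", {
  withr::local_seed(17)
  for (i in 1:60) {
    m <- sample(4:30, 1)
    gene <- rbinom(m, 1, runif(1, 0.1, 0.9))
    phen <- rbinom(m, 1, runif(1, 0.1, 0.9))
    expect_equal(fisher_association(gene, phen),
                 hyper_tail_oracle(gene, phen), tolerance = 1e-12)
  }
})

test_that("contingency cut-offs match boundary enumeration and are sound", {
  # n_in = 4, n_out = 4, alpha = 0.05: a gene with <= 3 ones inside
  # cannot reach p <= alpha even with no ones outside
  cut <- compute_cutoffs(0.05, 4, 4)
  p_at <- function(sin, sout) {
    hyper_tail_oracle(c(rep(1, sin), rep(0, 4 - sin),
                        rep(1, sout), rep(0, 4 - sout)),
                      c(rep(1, 4), rep(0, 4)))
  }
  # boundary by exhaustive enumeration of all (sigma_in, sigma_out) pairs
  exceed <- vapply(0:4, function(s) p_at(s, 0) > 0.05, logical(1))
  expect_identical(cut$min_sigma_in, max((0:4)[exceed]))
  expect_identical(cut$min_sigma_in, 3L)
  # alpha = 1: nothing can exceed p > 1, every gene is tested
  cut1 <- compute_cutoffs(1, 4, 4)
  expect_lt(cut1$min_sigma_in, 0L)
  expect_gt(cut1$max_sigma_out, 4L)
})

test_that("genes skipped by the cut-offs provably have p above alpha", {
  withr::local_seed(23)
  for (i in 1:40) {
    m <- sample(8:24, 1)
    n_in <- sample(2:(m - 2), 1)
    phen <- c(rep(1, n_in), rep(0, m - n_in))
    alpha <- sample(c(0.05, 0.01, 0.001), 1)
    cut <- compute_cutoffs(alpha, n_in, m - n_in)
    for (j in 1:5) {
      gene <- rbinom(m, 1, runif(1, 0.1, 0.9))
      sig_in <- sum(gene[phen == 1])
      sig_out <- sum(gene[phen == 0])
      skipped <- !(sig_in > cut$min_sigma_in && sig_out < cut$max_sigma_out)
      if (skipped) {
        expect_gt(fisher_association(gene, phen), alpha)
      }
    }
  }
})

test_that("extension recovers an exact embedded block and stores p-values", {
  B <- matrix(0L, 12, 16,
              dimnames = list(sprintf("g%d", 1:12), sprintf("s%d", 1:16)))
  B[2:6, 3:8] <- 1L
  attr(B, "direction") <- "up"
  seeds <- discover_seeds(B, min_support = 0.1, c2 = 2)
  b <- extend_bicluster(seeds[[1]], B, alpha = 0.01)
  expect_identical(sort(b$genes), sort(sprintf("g%d", 2:6)))
  expect_identical(sort(b$samples), sort(sprintf("s%d", 3:8)))
  expect_identical(b$direction, "up")
  expect_true(all(b$pvalues < 0.01))
  expect_equal(unname(b$pvalues[1]), 1 / choose(16, 6), tolerance = 1e-12)
})

test_that("extension adds a covering gene and deletes a weak seed gene", {
  # seed block g1-g3 on samples 1-8; g4 covers those 8 samples plus one
  # more (strongly associated, should be added); g3 is corrupted to
  # overlap the phenotype in only 2 of 8 samples (should be deleted)
  B <- matrix(0L, 6, 20,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:20)))
  B[1:3, 1:8] <- 1L
  B[3, ] <- 0L
  B[3, c(1, 2, 11, 12)] <- 1L
  B[4, 1:9] <- 1L
  seeds <- list(list(genes = 1:3, phenotype = phenotype_vector(1:2, B)))
  b <- extend_bicluster(seeds[[1]], B, alpha = 0.01)
  expect_true("g4" %in% b$genes)
  expect_false("g3" %in% b$genes)
  expect_setequal(b$genes, c("g1", "g2", "g4"))
})

test_that("a vanishing alpha drops every bicluster", {
  B <- make_three_block_binary()
  seeds <- discover_seeds(B, min_support = 0.1, c2 = 2)
  expect_null(extend_bicluster(seeds[[1]], B, alpha = 1e-300))
  expect_error(extend_bicluster(seeds[[1]], B, alpha = 0), "alpha")
})

test_that("extension is idempotent for a fixed phenotype vector", {
  withr::local_seed(29)
  for (i in 1:8) {
    B <- random_binary(20, 15, runif(1, 0.2, 0.5))
    rownames(B) <- sprintf("g%d", 1:20)
    colnames(B) <- sprintf("s%d", 1:15)
    seeds <- discover_seeds(B, min_support = 0.1, c2 = 1)
    if (!length(seeds)) next
    b1 <- extend_bicluster(seeds[[1]], B, alpha = 0.05)
    if (is.null(b1)) next
    seed2 <- list(genes = match(b1$genes, rownames(B)),
                  phenotype = seeds[[1]]$phenotype)
    b2 <- extend_bicluster(seed2, B, alpha = 0.05)
    expect_identical(sort(b1$genes), sort(b2$genes))
    expect_identical(b1$samples, b2$samples)
  }
})

test_that("overlap filtering follows the greedy largest-first rule", {
  A <- bicluster(sprintf("g%d", 1:10), sprintf("s%d", 1:10))
  Bsmall <- bicluster(sprintf("g%d", 1:4), sprintf("s%d", 1:4))
  # duplicate biclusters: only one survives
  expect_length(filter_overlap(list(A, A), L = 0.5), 1L)
  # disjoint biclusters all survive
  D <- bicluster(sprintf("g%d", 11:14), sprintf("s%d", 11:14))
  expect_length(filter_overlap(list(A, D), L = 0.5), 2L)
  # 4x4 fully inside 10x10: overlap 16 > 0.5 * 16, deleted at L = 0.5
  expect_length(filter_overlap(list(A, Bsmall), L = 0.5), 1L)
  # at L = 1 the strict "exceeds" comparison lets it survive
  expect_length(filter_overlap(list(A, Bsmall), L = 1), 2L)
})

test_that("surviving pairs always respect the overlap bound", {
  withr::local_seed(31)
  for (L in c(0.25, 0.5)) {
    for (i in 1:6) {
      bics <- random_bicluster_collection()
      kept <- filter_overlap(bics, L = L)
      if (length(kept) < 2) next
      for (a in seq_along(kept)) for (b in seq_along(kept)) {
        if (a >= b) next
        area <- length(intersect(kept[[a]]$genes, kept[[b]]$genes)) *
          length(intersect(kept[[a]]$samples, kept[[b]]$samples))
        smaller <- min(bicluster_size(kept[[a]]), bicluster_size(kept[[b]]))
        expect_lte(area, L * smaller + 1e-9)
      }
    }
  }
})
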