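# Shared fixtures and independent oracles for the test suite.

# Exact one-sided hypergeometric tail by direct enumeration from binomial
# coefficients (independent of stats::phyper, which the implementation
# uses): probability of >= sig_in of the gene's k ones falling inside the
# n_in phenotype samples when the k ones are placed uniformly among m.
hyper_tail_oracle <- function(gene, phen) {
  g <- gene != 0
  ph <- phen != 0
  m <- length(ph)
  n_in <- sum(ph)
  if (n_in == 0 || n_in == m) return(1)
  k <- sum(g)
  sig_in <- sum(g & ph)
  xs <- sig_in:min(k, n_in)
  xs <- xs[k - xs <= m - n_in]
  if (!length(xs)) return(0)
  sum(choose(n_in, xs) * choose(m - n_in, k - xs)) / choose(m, k)
}

# Random 0/1 matrix with given density.
random_binary <- function(n, m, density) {
  matrix(as.integer(stats::runif(n * m) < density), n, m)
}

# Canonical string keys for comparing gene-set lists set-for-set.
geneset_keys <- function(sets) {
  vapply(sets, function(s) paste(as.integer(s), collapse = "-"),
         character(1L))
}

# Three disjoint up-regulated gene blocks over 20 samples with supports
# 10/20, 6/20 and 4/20 (the classic seed-mining illustration): rows 1-3
# cover samples 1-10, rows 4-6 samples 11-16, rows 7-9 samples 17-20.
make_three_block_binary <- function() {
  B <- matrix(0L, 9, 20,
              dimnames = list(sprintf("g%d", 1:9), sprintf("s%d", 1:20)))
  B[1:3, 1:10] <- 1L
  B[4:6, 11:16] <- 1L
  B[7:9, 17:20] <- 1L
  B
}

# Same blocks as a log2 expression matrix (blocks at 2, background 0).
make_three_block_expression <- function() {
  E <- matrix(0, 9, 20,
              dimnames = list(sprintf("g%d", 1:9), sprintf("s%d", 1:20)))
  E[1:3, 1:10] <- 2
  E[4:6, 11:16] <- 2
  E[7:9, 17:20] <- 2
  E
}

# Random bicluster collection over a shared id universe, with forced
# duplication and nesting to stress the overlap filter.
random_bicluster_collection <- function(n = 12) {
  genes <- sprintf("g%02d", 1:40)
  samples <- sprintf("s%02d", 1:30)
  bics <- lapply(seq_len(n), function(i) {
    ng <- sample(2:15, 1)
    ns <- sample(2:12, 1)
    bicluster(sample(genes, ng), sample(samples, ns))
  })
  big <- bicluster(genes[1:20], samples[1:15])
  nested <- bicluster(genes[3:8], samples[2:7])       # inside big
  dup <- bicluster(big$genes, big$samples)            # duplicate of big
  c(bics, list(big, nested, dup))
}
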