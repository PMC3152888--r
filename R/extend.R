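#' One-sided Fisher exact association between a gene and a phenotype vector
#'
#' Builds the 2 x 2 contingency table of (gene bit in {1, 0}) x (phenotype
#' bit in {1, 0}) over samples and returns the exact one-sided
#' (over-representation) p-value: the hypergeometric upper-tail
#' probability of seeing at least the observed number of gene 1s inside
#' the phenotype samples. A degenerate phenotype (all ones or all zeros)
#' offers no contrast and returns 1 by convention.
#'
#' @param gene_row 0/1 (or logical) gene vector of length m >= 2.
#' @param phenotype 0/1 (or logical) phenotype vector of the same length.
#' @return A p-value in (0, 1].
#' @examples
#' fisher_association(c(1, 1, 1, 1, 0, 0, 0, 0),
#'                    c(1, 1, 1, 1, 0, 0, 0, 0))  # 1/choose(8, 4)
#' @export
fisher_association <- function(gene_row, phenotype) {
  m <- length(phenotype)
  if (length(gene_row) != m) stop("vectors must have equal length")
  if (m < 2L) stop("at least two samples are required")
  g <- gene_row != 0
  ph <- phenotype != 0
  n_in <- sum(ph)
  if (n_in == 0L || n_in == m) return(1)
  sig_in <- sum(g & ph)
  k <- sum(g)
  stats::phyper(sig_in - 1L, n_in, m - n_in, k, lower.tail = FALSE)
}

#' Precompute contingency-table cut-offs for the extension step
#'
#' Let sigma1,IN and sigma1,OUT be the number of 1s a gene vector has
#' inside and outside the bicluster samples. The one-sided p-value is
#' decreasing in sigma1,IN (at fixed sigma1,OUT) and increasing in
#' sigma1,OUT (at fixed sigma1,IN), so two scalar cut-offs suffice to
#' skip provably non-significant genes: the exact test needs to be applied
#' only to genes with `sigma1,IN > min_sigma_in` and
#' `sigma1,OUT < max_sigma_out`; every skipped gene has p > alpha.
#'
#' `min_sigma_in` is the largest sigma1,IN whose p-value stays above
#' `alpha` even in the most favorable case sigma1,OUT = 0 (it is -1 when
#' alpha >= 1, so that no gene is skipped). `max_sigma_out` is the
#' smallest sigma1,OUT whose p-value exceeds `alpha` even in the most
#' favorable case sigma1,IN = n_in (it is `n_out + 1` when no such count
#' exists).
#'
#' @param alpha Significance level.
#' @param n_in Number of bicluster samples (>= 1).
#' @param n_out Number of non-bicluster samples (>= 0).
#' @return A list with elements `min_sigma_in`, `max_sigma_out`, `alpha`,
#'   `n_in`, `n_out`.
#' @export
compute_cutoffs <- function(alpha, n_in, n_out) {
  stopifnot(n_in >= 1L, n_out >= 0L)
  p_at <- function(sin, sout) {
    stats::phyper(sin - 1L, n_in, n_out, sin + sout, lower.tail = FALSE)
  }
  s_in <- 0:n_in
  above <- p_at(s_in, 0L) > alpha
  min_sigma_in <- if (any(above)) max(s_in[above]) else -1L
  if (n_out > 0L) {
    s_out <- 0:n_out
    above <- p_at(n_in, s_out) > alpha
    max_sigma_out <- if (any(above)) min(s_out[above]) else n_out + 1L
  } else {
    max_sigma_out <- 1L  # sigma1,OUT is always 0 < 1: all genes tested
  }
  list(min_sigma_in = as.integer(min_sigma_in),
       max_sigma_out = as.integer(max_sigma_out),
       alpha = alpha, n_in = as.integer(n_in), n_out = as.integer(n_out))
}

#' Grow and prune a seed bicluster by Fisher exact tests
#'
#' One pass over all genes of the binary matrix with the seed's phenotype
#' vector held fixed: a gene enters the bicluster if its one-sided Fisher
#' p-value against the phenotype vector is below `alpha`; a seed gene
#' whose p-value is above `alpha` is removed. Genes excluded by the
#' precomputed contingency cut-offs ([compute_cutoffs()]) are never tested
#' (their p-value provably exceeds `alpha`). The per-gene p-values of the
#' retained genes are stored in the result.
#'
#' @param seed A list with `genes` (row indices) and `phenotype` (logical
#'   sample vector), as produced by [discover_seeds()].
#' @param B Binary matrix the seed was discovered in.
#' @param alpha Significance level in (0, 1).
#' @param verbose Log the number of genes added and removed.
#' @return A [bicluster()], or `NULL` when no gene passes the test (the
#'   bicluster is dropped).
#' @export
extend_bicluster <- function(seed, B, alpha, verbose = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)")
  }
  B <- ensure_dimnames(B)
  n <- nrow(B)
  phen <- seed$phenotype != 0
  m <- length(phen)
  n_in <- sum(phen)
  n_out <- m - n_in
  in_seed <- logical(n)
  in_seed[seed$genes] <- TRUE
  if (n_in == 0L || n_out == 0L) {
    if (verbose) message("degenerate phenotype vector (no contrast); bicluster dropped")
    return(NULL)
  }
  bits <- B != 0
  sig_in <- as.integer(rowSums(bits[, phen, drop = FALSE]))
  totals <- as.integer(rowSums(bits))
  sig_out <- totals - sig_in
  cut <- compute_cutoffs(alpha, n_in, n_out)
  testable <- sig_in > cut$min_sigma_in & sig_out < cut$max_sigma_out
  p <- rep(NA_real_, n)
  p[testable] <- stats::phyper(sig_in[testable] - 1L, n_in, n_out,
                               totals[testable], lower.tail = FALSE)
  keep <- testable & ((in_seed & p <= alpha) | (!in_seed & p < alpha))
  if (!any(keep)) {
    if (verbose) message("all genes failed the association test; bicluster dropped")
    return(NULL)
  }
  if (verbose) {
    message(sprintf("extension: %d added, %d removed, %d x %d bicluster",
                    sum(keep & !in_seed), sum(in_seed & !keep),
                    sum(keep), n_in))
  }
  bicluster(
    genes = rownames(B)[keep],
    samples = colnames(B)[phen],
    direction = bm_direction(B),
    pvalues = p[keep]
  )
}

#' Filter a bicluster collection for mutual overlap
#'
#' Greedy largest-first filtering: biclusters are visited in order of
#' decreasing size (ties broken by discovery order); a bicluster is
#' deleted when its overlap area with an already-kept bicluster — the
#' number of shared genes times the number of shared samples — strictly
#' exceeds `L` times its own size. After filtering, every surviving pair
#' satisfies overlap area <= L x the smaller of the two sizes.
#'
#' @param biclusters A list of [bicluster()]s or a [bicluster_set()].
#' @param L Maximum tolerated overlap fraction of the smaller bicluster,
#'   in (0, 1]. Typically 0.5; 0.25 for benchmark comparisons.
#' @return The surviving biclusters, same type as the input, in
#'   size-descending order.
#' @export
filter_overlap <- function(biclusters, L = 0.5) {
  if (!is.numeric(L) || length(L) != 1L || L <= 0 || L > 1) {
    stop("`L` must lie in (0, 1]")
  }
  was_set <- inherits(biclusters, "bicluster_set")
  bics <- unclass(biclusters)
  if (!length(bics)) return(biclusters)
  sizes <- vapply(bics, bicluster_size, numeric(1L))
  ord <- order(-sizes, seq_along(bics))
  kept <- list()
  for (i in ord) {
    b <- bics[[i]]
    size_b <- sizes[i]
    ok <- TRUE
    for (kb in kept) {
      area <- length(intersect(b$genes, kb$genes)) *
        length(intersect(b$samples, kb$samples))
      if (area > L * size_b + 1e-12) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept[[length(kept) + 1L]] <- b
  }
  if (was_set) {
    out <- bicluster_set(kept, alpha = attr(biclusters, "alpha"),
                         params = attr(biclusters, "params"))
    attr(out, "cs") <- attr(biclusters, "cs")
    out
  } else {
    kept
  }
}
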