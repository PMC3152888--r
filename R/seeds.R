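#' Discover seed biclusters by iterative maximal frequent gene-set mining
#'
#' Implements the seed-discovery step: the miner is applied repeatedly with
#' a descending support threshold. The first threshold is the support of
#' the gene with the highest support; every maximal frequent gene set
#' found becomes a seed (with its phenotype vector computed on the
#' original matrix) and its genes are removed from the working matrix.
#' The next threshold is the largest remaining single-gene support
#' strictly below the previous one, so the visited thresholds are strictly
#' decreasing; the loop stops when the threshold would fall below
#' `min_support` or no genes remain.
#'
#' @param B Binary matrix (genes x samples).
#' @param min_support Minimum support fraction in (0, 1] at which mining
#'   stops (thresholds below it are not visited).
#' @param c2 Minimum gene-set cardinality for a seed.
#' @param verbose If `TRUE`, log one line per iteration (threshold, number
#'   of maximal sets found, genes remaining).
#' @return A list of seeds, each a list with elements `genes` (sorted row
#'   indices), `phenotype` (logical sample vector), `support`, and
#'   `threshold` (the support level at which the seed was mined). The
#'   visited thresholds are attached as attribute `"thresholds"`. Seed
#'   gene sets are pairwise disjoint. An all-zero matrix yields an empty
#'   list.
#' @export
discover_seeds <- function(B, min_support = 0.05, c2 = 2L, verbose = FALSE) {
  stopifnot(is.matrix(B), nrow(B) >= 1L, ncol(B) >= 1L)
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    stop("`min_support` must lie in (0, 1]")
  }
  eps <- 1e-9
  n <- nrow(B)
  supports <- rowSums(B != 0) / ncol(B)
  remaining <- supports > 0
  seeds <- list()
  thresholds <- numeric(0)
  prev <- Inf
  while (any(remaining)) {
    below <- supports[remaining][supports[remaining] < prev - eps]
    if (!length(below)) break
    thr <- max(below)
    if (thr < min_support - eps) break
    idx <- which(remaining)
    sets <- mine_maximal_frequent(B[idx, , drop = FALSE], c1 = thr, c2 = c2)
    for (s in sets) {
      genes <- unname(sort(idx[s]))
      seeds[[length(seeds) + 1L]] <- list(
        genes = genes,
        phenotype = phenotype_vector(genes, B),
        support = attr(s, "support"),
        threshold = thr
      )
      remaining[genes] <- FALSE
    }
    thresholds <- c(thresholds, thr)
    if (verbose) {
      message(sprintf("seed mining: threshold %.4g, %d maximal set(s), %d gene(s) remaining",
                      thr, length(sets), sum(remaining)))
    }
    prev <- thr
  }
  attr(seeds, "thresholds") <- thresholds
  seeds
}

#' Run binarization, seed discovery and extension for one direction
#'
#' Composes [binarize()], [discover_seeds()] and [extend_bicluster()] for a
#' single regulation direction. Up- and down-regulation runs are
#' independent; the full pipeline ([debi()]) concatenates their outputs
#' before overlap filtering.
#'
#' @param E Numeric expression matrix.
#' @param c Fold-change cut-off (> 1).
#' @param direction `"up"` or `"down"`.
#' @param alpha Significance level for the Fisher extension, in (0, 1).
#' @param min_support,c2 Seed-discovery parameters, see [discover_seeds()].
#' @param L Optional overlap fraction; if non-`NULL`, [filter_overlap()] is
#'   applied to this direction's biclusters alone.
#' @param verbose Log progress.
#' @return A [bicluster_set()] (unscored).
#' @export
run_direction <- function(E, c = 2, direction = c("up", "down"),
                          alpha = 0.01, min_support = 0.05, c2 = 2L,
                          L = NULL, verbose = FALSE) {
  direction <- match.arg(direction)
  B <- binarize(E, c = c, direction = direction)
  B <- ensure_dimnames(B)
  seeds <- discover_seeds(B, min_support = min_support, c2 = c2,
                          verbose = verbose)
  bics <- list()
  for (seed in seeds) {
    b <- extend_bicluster(seed, B, alpha = alpha, verbose = verbose)
    if (!is.null(b)) bics[[length(bics) + 1L]] <- b
  }
  if (!is.null(L)) bics <- filter_overlap(bics, L = L)
  bicluster_set(unclass(bics), alpha = alpha,
                params = list(cutoff = c, direction = direction,
                              min_support = min_support, c2 = c2))
}

ensure_dimnames <- function(B) {
  if (is.null(rownames(B))) {
    rownames(B) <- sprintf("g%d", seq_len(nrow(B)))
  }
  if (is.null(colnames(B))) {
    colnames(B) <- sprintf("s%d", seq_len(ncol(B)))
  }
  B
}
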