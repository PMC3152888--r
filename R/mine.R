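#' Support of genes in a binary matrix
#'
#' The support of a gene is the fraction of samples in which its 0/1
#' regulation vector equals 1.
#'
#' @param x A 0/1 (or logical) vector, or a binary matrix (genes in rows).
#' @return A single fraction for a vector input, or a named vector of
#'   per-gene supports for a matrix input.
#' @examples
#' gene_support(c(1, 1, 0, 1))  # 0.75
#' @export
gene_support <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) < 1L) stop("matrix must have at least one sample")
    return(rowSums(x != 0) / ncol(x))
  }
  if (!length(x)) stop("gene vector must have length >= 1")
  sum(x != 0) / length(x)
}

#' Phenotype vector of a gene set
#'
#' The phenotype vector of a gene set is the element-wise logical AND of
#' the genes' binary rows; its 1-positions are the samples in which every
#' gene of the set is regulated. The support of the gene set is the
#' fraction of 1s in its phenotype vector.
#'
#' @param genes Row indices or row names of `B` (non-empty).
#' @param B Binary matrix (genes x samples).
#' @return A logical vector of length `ncol(B)`, named by sample.
#' @export
phenotype_vector <- function(genes, B) {
  if (!length(genes)) {
    stop("the phenotype vector of an empty gene set is undefined")
  }
  sub <- B[genes, , drop = FALSE]
  out <- colSums(sub != 0) == nrow(sub)
  names(out) <- colnames(B)
  out
}

## Smallest integer count t such that t/m clears the support threshold c1.
## Supports are rationals k/m; "larger than c1" is applied with a small
## epsilon so that a support exactly equal to c1 counts as frequent
## (thresholds in the seed schedule are themselves observed supports).
support_count_threshold <- function(c1, m) {
  max(1L, as.integer(ceiling(c1 * m - 1e-9)))
}

canonical_geneset_order <- function(sets, supports) {
  if (!length(sets)) return(integer(0))
  keys <- vapply(sets, function(s) {
    paste(sprintf("%06d", s), collapse = ",")
  }, character(1L))
  order(-supports, keys)
}

#' Mine maximal frequent gene sets
#'
#' A gene set is (c1, c2)-frequent when the support of its phenotype
#' vector clears `c1` and its cardinality is at least `c2`; it is maximal
#' frequent when no strict superset is frequent. The miner performs a
#' depth-first traversal of the set-enumeration tree over genes ordered by
#' decreasing support, pruning with the anti-monotonicity of support
#' (every subset of a frequent set is frequent), and checks full
#' maximality of each candidate against all remaining genes.
#'
#' @param B Binary matrix (genes x samples).
#' @param c1 Minimum support fraction in (0, 1]. A set whose support
#'   equals `c1` is counted as frequent (exact rational comparison on
#'   counts).
#' @param c2 Minimum gene-set cardinality (>= 1).
#' @param strict_cardinality If `TRUE`, require cardinality strictly
#'   greater than `c2` instead of at least `c2`.
#' @return A list of sorted integer vectors of row indices, each carrying a
#'   `support` attribute, in canonical order: decreasing support, ties
#'   broken lexicographically on the index vectors. May be empty.
#' @seealso [brute_force_maximal()] for the exhaustive reference
#'   implementation used as a test oracle.
#' @export
mine_maximal_frequent <- function(B, c1, c2 = 1L, strict_cardinality = FALSE) {
  stopifnot(is.matrix(B), nrow(B) >= 1L, ncol(B) >= 1L)
  if (!is.numeric(c1) || length(c1) != 1L || c1 <= 0 || c1 > 1) {
    stop("`c1` must lie in (0, 1]")
  }
  c2 <- as.integer(c2)
  if (c2 < 1L) stop("`c2` must be >= 1")
  min_card <- if (strict_cardinality) c2 + 1L else c2
  m <- ncol(B)
  tmin <- support_count_threshold(c1, m)
  totals <- as.integer(rowSums(B != 0))
  univ <- which(totals >= tmin)
  if (!length(univ)) return(list())
  univ <- univ[order(-totals[univ], univ)]
  rows <- lapply(univ, function(i) B[i, ] != 0)
  k <- length(univ)
  maximal <- list()
  max_keys <- character(0)

  is_maximal <- function(members, v) {
    ## no gene outside the set may extend it frequently
    for (g in seq_len(k)) {
      if (!members[g] && sum(v & rows[[g]]) >= tmin) return(FALSE)
    }
    TRUE
  }

  dfs <- function(set_pos, v, cand) {
    ext <- cand[vapply(cand, function(g) sum(v & rows[[g]]) >= tmin,
                       logical(1L))]
    if (!length(ext)) {
      if (length(set_pos) >= min_card) {
        members <- logical(k)
        members[set_pos] <- TRUE
        if (is_maximal(members, v)) {
          idx <- sort(univ[set_pos])
          s <- structure(idx, support = sum(v) / m)
          maximal[[length(maximal) + 1L]] <<- s
        }
      }
      return(invisible(NULL))
    }
    for (j in seq_along(ext)) {
      g <- ext[j]
      dfs(c(set_pos, g), v & rows[[g]], ext[-seq_len(j)])
    }
    invisible(NULL)
  }

  for (j in seq_len(k)) {
    dfs(j, rows[[j]], if (j < k) (j + 1L):k else integer(0))
  }
  sup <- vapply(maximal, attr, numeric(1L), "support")
  maximal[canonical_geneset_order(maximal, sup)]
}

#' Exhaustive maximal frequent gene-set search (test oracle)
#'
#' Enumerates every non-empty gene subset, keeps the frequent ones, and
#' returns those with no frequent strict superset. Same contract and
#' canonical ordering as [mine_maximal_frequent()], but exponential in the
#' number of genes; refuses matrices with more than 20 genes.
#'
#' @inheritParams mine_maximal_frequent
#' @return A list of sorted integer index vectors with `support`
#'   attributes, in canonical order.
#' @export
brute_force_maximal <- function(B, c1, c2 = 1L, strict_cardinality = FALSE) {
  stopifnot(is.matrix(B), nrow(B) >= 1L, ncol(B) >= 1L)
  n <- nrow(B)
  if (n > 20L) stop("brute force refuses matrices with more than 20 genes")
  c2 <- as.integer(c2)
  min_card <- if (strict_cardinality) c2 + 1L else c2
  m <- ncol(B)
  tmin <- support_count_threshold(c1, m)
  logical_B <- B != 0
  freq <- new.env(parent = emptyenv())
  freq_sets <- list()
  freq_sup <- numeric(0)
  for (mask in seq_len(2^n - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) != 0L)
    cnt <- sum(colSums(logical_B[sel, , drop = FALSE]) == length(sel))
    if (cnt >= tmin) {
      key <- paste(sel, collapse = "-")
      assign(key, TRUE, envir = freq)
      if (length(sel) >= min_card) {
        freq_sets[[length(freq_sets) + 1L]] <- sel
        freq_sup <- c(freq_sup, cnt / m)
      }
    }
  }
  keep <- vapply(freq_sets, function(s) {
    for (g in setdiff(seq_len(n), s)) {
      key <- paste(sort(c(s, g)), collapse = "-")
      if (exists(key, envir = freq, inherits = FALSE)) return(FALSE)
    }
    TRUE
  }, logical(1L))
  sets <- freq_sets[keep]
  sup <- freq_sup[keep]
  sets <- Map(function(s, p) structure(s, support = p), sets, sup)
  sets[canonical_geneset_order(sets, sup)]
}
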