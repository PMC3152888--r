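#' Generate a synthetic expression matrix with implanted biclusters
#'
#' Emulates the classic implanted-bicluster benchmark: a background of
#' zeros (log2 scale) with `n_biclusters` blocks of dimension
#' `bic_rows x bic_cols` placed along the diagonal. With
#' `overlap_degree = 0` consecutive blocks are disjoint; with degree d
#' consecutive blocks are shifted by `bic_rows - d` rows and
#' `bic_cols - d` columns, so adjacent implanted biclusters share exactly
#' d genes and d samples.
#'
#' Block values: under the constant model every block cell is `level`
#' (default 2.0, i.e. 4-fold up-regulation in log2 units). Under the
#' additive model distinct row and column offsets (steps of 0.1) are added
#' to `level`, so expression varies over the conditions while every block
#' cell stays above the binarization threshold `log2(2) = 1` at the
#' default fold-change cut-off of 2. Gaussian noise with standard
#' deviation `noise * level` is added to every matrix cell. With
#' `binary = TRUE` a 0/1 matrix is returned instead, with each bit
#' flipped independently with probability `noise`.
#'
#' @param n_genes,n_samples Matrix dimensions (default 100 x 50).
#' @param n_biclusters Number of implanted blocks (default 10).
#' @param bic_rows,bic_cols Block dimensions (default 10 x 5).
#' @param model `"constant"` or `"additive"`.
#' @param noise Noise level >= 0 (Gaussian sd as a fraction of `level`, or
#'   bit-flip probability in binary mode).
#' @param overlap_degree Number of genes and samples shared by consecutive
#'   blocks; must be smaller than `min(bic_rows, bic_cols)`.
#' @param level Block expression level in log2 units (default 2).
#' @param binary Return a 0/1 matrix with flip noise instead of an
#'   expression matrix.
#' @param seed Optional integer; the scenario is deterministic under a
#'   fixed seed.
#' @return A list of class `"debi_scenario"` with elements `exprs` (the
#'   matrix), `truth` (a [bicluster_set()] of the implanted biclusters)
#'   and `spec` (the generating parameters).
#' @export
generate_scenario <- function(n_genes = 100L, n_samples = 50L,
                              n_biclusters = 10L, bic_rows = 10L,
                              bic_cols = 5L,
                              model = c("constant", "additive"),
                              noise = 0, overlap_degree = 0L,
                              level = 2, binary = FALSE, seed = NULL) {
  model <- match.arg(model)
  stopifnot(noise >= 0, n_biclusters >= 1L)
  overlap_degree <- as.integer(overlap_degree)
  if (overlap_degree < 0L || overlap_degree >= min(bic_rows, bic_cols)) {
    stop("`overlap_degree` must lie in [0, min(bic_rows, bic_cols) - 1]")
  }
  row_step <- bic_rows - overlap_degree
  col_step <- bic_cols - overlap_degree
  last_row <- (n_biclusters - 1L) * row_step + bic_rows
  last_col <- (n_biclusters - 1L) * col_step + bic_cols
  if (last_row > n_genes || last_col > n_samples) {
    stop(sprintf("implanted blocks exceed the matrix: need %d x %d, have %d x %d",
                 last_row, last_col, n_genes, n_samples))
  }
  build <- function() {
    gene_ids <- sprintf("g%03d", seq_len(n_genes))
    sample_ids <- sprintf("s%03d", seq_len(n_samples))
    E <- matrix(0, n_genes, n_samples, dimnames = list(gene_ids, sample_ids))
    truth <- vector("list", n_biclusters)
    for (k in seq_len(n_biclusters)) {
      rows <- (k - 1L) * row_step + seq_len(bic_rows)
      cols <- (k - 1L) * col_step + seq_len(bic_cols)
      block <- matrix(level, bic_rows, bic_cols)
      if (model == "additive") {
        block <- block + outer(0.1 * (seq_len(bic_rows) - 1L),
                               0.1 * (seq_len(bic_cols) - 1L), `+`)
      }
      E[rows, cols] <- block
      truth[[k]] <- bicluster(gene_ids[rows], sample_ids[cols],
                              direction = "up")
    }
    if (binary) {
      Bbits <- (E >= log2(2)) + 0L
      if (noise > 0) {
        flips <- matrix(stats::runif(n_genes * n_samples) < noise,
                        n_genes, n_samples)
        Bbits <- abs(Bbits - flips)
      }
      E <- matrix(as.integer(Bbits), n_genes, n_samples,
                  dimnames = list(gene_ids, sample_ids))
    } else if (noise > 0) {
      E <- E + matrix(stats::rnorm(n_genes * n_samples, 0, noise * level),
                      n_genes, n_samples)
    }
    structure(
      list(exprs = E,
           truth = bicluster_set(truth),
           spec = list(n_genes = n_genes, n_samples = n_samples,
                       n_biclusters = n_biclusters, bic_rows = bic_rows,
                       bic_cols = bic_cols, model = model, noise = noise,
                       overlap_degree = overlap_degree, level = level,
                       binary = binary, seed = seed)),
      class = "debi_scenario"
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

gene_sets_of <- function(x) lapply(x, function(b) unique(as.character(b$genes)))

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Gene-dimension recovery score between bicluster sets
#'
#' For each true bicluster, the best Jaccard similarity of its gene set to
#' any found bicluster's gene set is taken; the score is the average over
#' the true biclusters. It measures how well the implanted biclusters are
#' recovered, without penalizing extra found biclusters. Swapping the
#' arguments gives the relevance orientation (how well each found
#' bicluster matches some true one).
#'
#' @param found A [bicluster_set()] (or list of objects with a `genes`
#'   element); may be empty (score 0).
#' @param truth The reference bicluster set (non-empty).
#' @return A score in \[0, 1\].
#' @export
prelic_recovery <- function(found, truth) {
  tg <- gene_sets_of(truth)
  if (!length(tg)) stop("`truth` must be non-empty")
  fg <- gene_sets_of(found)
  if (!length(fg)) return(0)
  mean(vapply(tg, function(t) {
    max(vapply(fg, jaccard, numeric(1L), t))
  }, numeric(1L)))
}

cell_jaccard <- function(a, b) {
  inter <- length(intersect(a$genes, b$genes)) *
    length(intersect(a$samples, b$samples))
  u <- bicluster_size(a) + bicluster_size(b) - inter
  if (u == 0) 0 else inter / u
}

## Total weight of the maximum-weight one-to-one assignment for a
## similarity matrix (rows x cols), solved exactly via weighted bipartite
## matching.
assignment_weight <- function(sim) {
  k1 <- nrow(sim)
  k2 <- ncol(sim)
  pos <- which(sim > 0, arr.ind = TRUE)
  if (!nrow(pos)) return(0)
  edges <- as.vector(rbind(pos[, 1L], k1 + pos[, 2L]))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, k1), rep(TRUE, k2)),
                                    edges, directed = FALSE)
  m <- igraph::max_bipartite_match(g, weights = sim[pos])
  m$matching_weight
}

## Greedy matching (largest similarity first, rows/cols used once); lower
## bound on the optimal assignment, used as fallback for very large sets.
greedy_match_weight <- function(sim) {
  total <- 0
  repeat {
    best <- which.max(sim)
    if (!length(best) || sim[best] <= 0) break
    idx <- arrayInd(best, dim(sim))
    total <- total + sim[best]
    sim[idx[1L], ] <- -Inf
    sim[, idx[2L]] <- -Inf
  }
  total
}

#' Consensus score between two bicluster sets
#'
#' Pairwise similarities are Jaccard indices on the (gene, sample) cell
#' sets of the biclusters; the biclusters of one set are assigned
#' one-to-one to biclusters of the other so as to maximize the summed
#' similarity (exact weighted bipartite matching), and the sum is divided
#' by the size of the larger set. Splitting or over-calling biclusters is
#' thereby penalized. Two empty sets score 1 by convention; exactly one
#' empty set scores 0. The score is symmetric in its arguments.
#'
#' @param found,truth Bicluster sets ([bicluster_set()] or lists of
#'   objects with `genes` and `samples`).
#' @return A score in \[0, 1\].
#' @export
hochreiter_consensus <- function(found, truth) {
  k1 <- length(found)
  k2 <- length(truth)
  if (k1 == 0L && k2 == 0L) return(1)
  if (k1 == 0L || k2 == 0L) return(0)
  sim <- matrix(0, k1, k2)
  for (i in seq_len(k1)) {
    for (j in seq_len(k2)) {
      sim[i, j] <- cell_jaccard(found[[i]], truth[[j]])
    }
  }
  w <- if (max(k1, k2) > 1000L) greedy_match_weight(sim) else
    assignment_weight(sim)
  w / max(k1, k2)
}

#' Run the synthetic benchmark
#'
#' For every scenario (model x noise level, or model x overlap degree) and
#' replicate: generate a matrix with implanted biclusters, run the full
#' pipeline, and score the found biclusters against the truth with the
#' recovery score (both orientations) and the consensus score. Overlap
#' scenarios are noise-free and use a 100 x 100 matrix with ten 10 x 10
#' blocks; noise scenarios use the 100 x 50 matrix with ten 10 x 5 blocks.
#'
#' @param models Subset of `c("constant", "additive")`.
#' @param noise_levels Noise grid for the noise scenarios (ignored when
#'   `overlap_degrees` is given).
#' @param overlap_degrees Optional overlap grid; when non-`NULL` the
#'   overlap scenarios are run instead of the noise scenarios.
#' @param n_replicates Replicates per grid point (default 10).
#' @param L Overlap-filter fraction used on the found biclusters
#'   (default 0.25, the benchmark convention).
#' @param alpha `"select"` (default) or a fixed level in (0, 1).
#' @param grid Alpha grid when `alpha = "select"`.
#' @param c,min_support,c2,n_random Pipeline parameters, see [debi()].
#' @param seed Base integer seed; per-replicate seeds are derived from it.
#' @param verbose Log one line per replicate.
#' @return A data frame with one row per (scenario, replicate):
#'   `scenario_id`, `model`, `noise`, `overlap`, `replicate`, `seed`,
#'   `n_found`, `recovery`, `relevance`, `consensus`.
#' @export
run_benchmark <- function(models = c("constant", "additive"),
                          noise_levels = c(0, 0.05, 0.1),
                          overlap_degrees = NULL, n_replicates = 10L,
                          L = 0.25, alpha = "select", grid = alpha_grid(),
                          c = 2, min_support = 0.05, c2 = 2L,
                          n_random = 500L, seed = 1L, verbose = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(overlap_degrees)) {
    grid_df <- expand.grid(model = models, noise = noise_levels,
                           overlap = 0L, stringsAsFactors = FALSE)
  } else {
    grid_df <- expand.grid(model = models, noise = 0,
                           overlap = as.integer(overlap_degrees),
                           stringsAsFactors = FALSE)
  }
  rows <- list()
  counter <- 0L
  for (i in seq_len(nrow(grid_df))) {
    model <- grid_df$model[i]
    noise <- grid_df$noise[i]
    ov <- grid_df$overlap[i]
    for (rep in seq_len(n_replicates)) {
      counter <- counter + 1L
      rep_seed <- as.integer((as.numeric(seed) + 104729 * counter) %%
                               2147483647)
      sc <- if (is.null(overlap_degrees)) {
        generate_scenario(model = model, noise = noise, seed = rep_seed)
      } else {
        generate_scenario(n_genes = 100L, n_samples = 100L,
                          bic_rows = 10L, bic_cols = 10L,
                          model = model, noise = 0,
                          overlap_degree = ov, seed = rep_seed)
      }
      res <- debi(sc$exprs, c = c, alpha = alpha, grid = grid,
                  min_support = min_support, c2 = c2, L = L,
                  n_random = n_random, seed = rep_seed)
      rows[[counter]] <- data.frame(
        scenario_id = sprintf("%s_noise%g_ov%d", model, noise, ov),
        model = model, noise = noise, overlap = ov, replicate = rep,
        seed = rep_seed, n_found = length(res),
        recovery = prelic_recovery(res, sc$truth),
        relevance = if (length(res)) prelic_recovery(sc$truth, res) else 0,
        consensus = hochreiter_consensus(res, sc$truth),
        stringsAsFactors = FALSE
      )
      if (verbose) {
        message(sprintf("%s noise=%g overlap=%d rep %d: %d found, recovery %.3f",
                        model, noise, ov, rep, length(res),
                        rows[[counter]]$recovery))
      }
    }
  }
  do.call(rbind, rows)
}
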