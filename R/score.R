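#' Raw bicluster score
#'
#' The raw score I of a bicluster is the negative sum of the natural-log
#' p-values of its genes. It grows with both the number of genes and the
#' strength of their association with the bicluster samples.
#'
#' @param b A [bicluster()] with stored p-values.
#' @return A non-negative number.
#' @examples
#' b <- bicluster("g1", "s1", pvalues = 0.1)
#' bicluster_score(b)  # -log(0.1)
#' @export
bicluster_score <- function(b) {
  p <- b$pvalues
  if (is.null(p)) stop("bicluster has no stored p-values")
  if (any(is.na(p)) || any(p <= 0)) {
    stop("all p-values must lie in (0, 1]")
  }
  -sum(log(p))
}

#' Expected raw score under random phenotype vectors
#'
#' Estimates the size-dependent null expectation of the raw score I by
#' randomization: random phenotype vectors with the same number of 1s as
#' the bicluster has samples are drawn (uniform sample subsets, without
#' replacement), the one-sided Fisher p-value of every bicluster gene
#' against each random vector is computed, and the mean of the resulting
#' random I scores is returned.
#'
#' @param b A [bicluster()].
#' @param B The binary matrix the bicluster lives in (must contain all of
#'   `b$genes` among its row names).
#' @param n_random Number of random phenotype vectors (default 500).
#' @param seed Optional integer; when given, the draws are made under this
#'   seed without disturbing the caller's RNG state.
#' @return The mean random I score (>= 0).
#' @export
expected_score <- function(b, B, n_random = 500L, seed = NULL) {
  stopifnot(n_random >= 1L)
  B <- ensure_dimnames(B)
  if (!all(b$genes %in% rownames(B))) {
    stop("bicluster genes missing from the binary matrix")
  }
  draw <- function() {
    m <- ncol(B)
    n_in <- length(b$samples)
    if (n_in >= m) return(0)  # degenerate: no contrast, all p = 1
    bits <- (B[b$genes, , drop = FALSE] != 0) + 0
    ind <- matrix(0, m, n_random)
    for (r in seq_len(n_random)) {
      ind[sample.int(m, n_in), r] <- 1
    }
    sig_in <- bits %*% ind
    totals <- rowSums(bits)
    p <- stats::phyper(sig_in - 1, n_in, m - n_in,
                       matrix(totals, nrow(bits), n_random),
                       lower.tail = FALSE)
    mean(colSums(-log(p)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Total biclustering score
#'
#' The total score CS of a scored bicluster set is the sum of the
#' normalized scores NI over its biclusters.
#'
#' @param sets A scored [bicluster_set()] (each bicluster carries `nscore`).
#' @return A non-negative number (0 for an empty set).
#' @export
total_score <- function(sets) {
  if (!length(sets)) return(0)
  ni <- vapply(sets, function(b) b$nscore, numeric(1L))
  if (any(is.na(ni))) stop("bicluster set has not been scored")
  sum(ni)
}

## Score every bicluster of a set in place: I, E[I] by randomization, and
## NI = I / E[I] (0 when E[I] = 0, which only happens for signal-free
## genes whose random p-values are all 1). `Bmap` maps direction -> binary
## matrix.
score_bicluster_set <- function(bs, Bmap, n_random = 500L) {
  for (i in seq_along(bs)) {
    b <- bs[[i]]
    B <- Bmap[[b$direction]]
    if (is.null(B)) stop("no binary matrix for direction ", b$direction)
    iv <- bicluster_score(b)
    ev <- expected_score(b, B, n_random = n_random)
    ni <- if (ev > 0) iv / ev else {
      warning("expected score is 0; NI set to 0 for a signal-free bicluster")
      0
    }
    b$score <- iv
    b$nscore <- ni
    bs[[i]] <- b
  }
  attr(bs, "cs") <- total_score(bs)
  bs
}

#' Default significance-level grid for alpha selection
#'
#' @param full If `TRUE`, the dense grid `10^-(2:100)`; otherwise a
#'   7-point logarithmic subset `10^-c(2,4,8,16,32,64,100)` on which the
#'   slowly varying total score CS is evaluated by default.
#' @return A decreasing numeric vector of alpha values.
#' @export
alpha_grid <- function(full = FALSE) {
  if (full) 10^-(2:100) else 10^-c(2, 4, 8, 16, 32, 64, 100)
}

#' Select the significance level maximizing the total score
#'
#' Runs the full pipeline (binarization, seed discovery, Fisher extension,
#' overlap filtering, randomization-normalized scoring) once per candidate
#' alpha and returns the alpha with the largest total score CS. The RNG is
#' reset to `seed` before each alpha's scoring pass, so the result does
#' not depend on the grid order and each alpha's run is independently
#' reproducible.
#'
#' @param E Numeric expression matrix (or 0/1 matrix with
#'   `prebinarized = TRUE`).
#' @param grid Candidate alpha values in (0, 1); see [alpha_grid()].
#' @param c Fold-change cut-off for binarization.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @param min_support,c2 Seed-discovery parameters.
#' @param L Overlap-filter fraction.
#' @param n_random Randomization replicates per bicluster for NI.
#' @param seed Integer seed for the randomization draws.
#' @param prebinarized Treat `E` as an already 0/1 matrix (no
#'   thresholding; single run tagged `"as_given"`).
#' @param verbose Log progress.
#' @return A list with `alpha` (the argmax, ties broken toward the
#'   smaller value), `cs_table` (data frame with columns `alpha`,
#'   `n_biclusters`, `cs`), and `result` (the scored [bicluster_set()] at
#'   the selected alpha). If every alpha yields zero biclusters, the
#'   largest alpha is returned with a warning.
#' @export
select_alpha <- function(E, grid = alpha_grid(), c = 2,
                         direction = c("both", "up", "down"),
                         min_support = 0.05, c2 = 2L, L = 0.5,
                         n_random = 500L, seed = 1L,
                         prebinarized = FALSE, verbose = FALSE) {
  direction <- match.arg(direction)
  if (!length(grid) || any(grid <= 0 | grid >= 1)) {
    stop("`grid` must be a non-empty vector of values in (0, 1)")
  }
  prep <- prepare_seeds(E, c = c, direction = direction,
                        min_support = min_support, c2 = c2,
                        prebinarized = prebinarized, verbose = verbose)
  results <- vector("list", length(grid))
  cs <- numeric(length(grid))
  nb <- integer(length(grid))
  for (i in seq_along(grid)) {
    bs <- extend_filter_score(prep, alpha = grid[i], L = L,
                              n_random = n_random, seed = seed,
                              verbose = verbose)
    results[[i]] <- bs
    cs[i] <- attr(bs, "cs")
    nb[i] <- length(bs)
    if (verbose) {
      message(sprintf("alpha = %g: %d bicluster(s), CS = %.4g",
                      grid[i], nb[i], cs[i]))
    }
  }
  tab <- data.frame(alpha = grid, n_biclusters = nb, cs = cs)
  if (all(nb == 0L)) {
    warning("no biclusters at any alpha; returning the largest alpha")
    best <- which.max(grid)
  } else {
    top <- max(cs)
    cand <- which(cs >= top - 1e-12 * max(1, abs(top)))
    best <- cand[which.min(grid[cand])]
  }
  list(alpha = grid[best], cs_table = tab, result = results[[best]])
}

## Binarize (per direction) and mine seeds once; alpha-independent.
prepare_seeds <- function(E, c, direction, min_support, c2,
                          prebinarized = FALSE, verbose = FALSE) {
  if (prebinarized) {
    B <- ensure_dimnames(as_binary_matrix(E))
    dirs <- "as_given"
    Bmap <- list(as_given = B)
  } else {
    dirs <- if (direction == "both") c("up", "down") else direction
    Bmap <- lapply(stats::setNames(dirs, dirs), function(d) {
      ensure_dimnames(binarize(E, c = c, direction = d))
    })
  }
  seeds <- lapply(Bmap, discover_seeds, min_support = min_support,
                  c2 = c2, verbose = verbose)
  list(Bmap = Bmap, seeds = seeds, cutoff = if (prebinarized) NA_real_ else c,
       min_support = min_support, c2 = c2, directions = dirs)
}

## Extension, concatenation across directions, overlap filter, scoring.
extend_filter_score <- function(prep, alpha, L, n_random, seed,
                                verbose = FALSE) {
  bics <- list()
  for (d in names(prep$Bmap)) {
    B <- prep$Bmap[[d]]
    for (seed_set in prep$seeds[[d]]) {
      b <- extend_bicluster(seed_set, B, alpha = alpha, verbose = verbose)
      if (!is.null(b)) bics[[length(bics) + 1L]] <- b
    }
  }
  bics <- filter_overlap(bics, L = L)
  bs <- bicluster_set(bics, alpha = alpha,
                      params = list(cutoff = prep$cutoff,
                                    direction = paste(prep$directions,
                                                      collapse = ","),
                                    min_support = prep$min_support,
                                    c2 = prep$c2, L = L,
                                    n_random = n_random, seed = seed))
  withr::with_seed(seed, score_bicluster_set(bs, prep$Bmap,
                                             n_random = n_random))
}

#' Run the full biclustering pipeline
#'
#' End-to-end run: binarize the expression matrix into up- and/or
#' down-regulation indicator matrices, mine seed gene sets with a
#' descending support threshold, extend and prune each seed with Fisher
#' exact tests at significance `alpha`, concatenate the directions,
#' filter the collection for overlap, and score each surviving bicluster
#' (raw score I, randomization mean, normalized score NI; their sum is
#' the total score CS attached as attribute `"cs"`).
#'
#' @inheritParams select_alpha
#' @param alpha Fixed significance level in (0, 1), or `"select"` to pick
#'   it from `grid` by maximizing CS (see [select_alpha()]); the CS table
#'   is then attached as attribute `"cs_table"`.
#' @return A scored [bicluster_set()].
#' @examples
#' sc <- generate_scenario(n_genes = 40, n_samples = 20, n_biclusters = 4,
#'                         bic_rows = 10, bic_cols = 5, seed = 1)
#' res <- debi(sc$exprs, alpha = 0.001, n_random = 50, seed = 1)
#' length(res)
#' @export
debi <- function(E, c = 2, direction = c("both", "up", "down"),
                 alpha = "select", grid = alpha_grid(),
                 min_support = 0.05, c2 = 2L, L = 0.5,
                 n_random = 500L, seed = 1L, prebinarized = FALSE,
                 verbose = FALSE) {
  direction <- match.arg(direction)
  if (identical(alpha, "select")) {
    sel <- select_alpha(E, grid = grid, c = c, direction = direction,
                        min_support = min_support, c2 = c2, L = L,
                        n_random = n_random, seed = seed,
                        prebinarized = prebinarized, verbose = verbose)
    out <- sel$result
    attr(out, "cs_table") <- sel$cs_table
    return(out)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1) or be \"select\"")
  }
  prep <- prepare_seeds(E, c = c, direction = direction,
                        min_support = min_support, c2 = c2,
                        prebinarized = prebinarized, verbose = verbose)
  extend_filter_score(prep, alpha = alpha, L = L, n_random = n_random,
                      seed = seed, verbose = verbose)
}
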