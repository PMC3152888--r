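#' Construct a bicluster
#'
#' A bicluster is a gene subset together with a sample subset (the
#' 1-positions of its phenotype vector) in which every retained gene is
#' significantly over-represented, plus bookkeeping: the regulation
#' direction of the binary matrix it was found in and the per-gene Fisher
#' p-values.
#'
#' @param genes Character vector of gene identifiers (non-empty, unique).
#' @param samples Character vector of sample identifiers (non-empty, unique).
#' @param direction `"up"`, `"down"` or `"as_given"`.
#' @param pvalues Numeric vector of per-gene association p-values in (0, 1],
#'   parallel to `genes` (optional, may be `NULL` for truth sets).
#' @param score Raw score I (negative sum of log p-values), or `NA`.
#' @param nscore Randomization-normalized score NI, or `NA`.
#' @return An object of class `"bicluster"`.
#' @export
bicluster <- function(genes, samples, direction = "as_given",
                      pvalues = NULL, score = NA_real_, nscore = NA_real_) {
  genes <- as.character(genes)
  samples <- as.character(samples)
  if (!length(genes) || anyDuplicated(genes)) {
    stop("`genes` must be a non-empty vector of unique identifiers")
  }
  if (!length(samples) || anyDuplicated(samples)) {
    stop("`samples` must be a non-empty vector of unique identifiers")
  }
  if (!is.null(pvalues)) {
    pvalues <- as.numeric(pvalues)
    if (length(pvalues) != length(genes)) {
      stop("`pvalues` must be parallel to `genes`")
    }
    if (any(!is.na(pvalues) & (pvalues <= 0 | pvalues > 1))) {
      stop("p-values must lie in (0, 1]")
    }
    names(pvalues) <- genes
  }
  structure(
    list(genes = genes, samples = samples, direction = direction,
         pvalues = pvalues, score = score, nscore = nscore),
    class = "bicluster"
  )
}

#' Size of a bicluster
#'
#' The size is the number of genes times the number of samples, i.e. the
#' area of the submatrix the bicluster spans.
#'
#' @param b A [bicluster()].
#' @return A single number.
#' @export
bicluster_size <- function(b) {
  length(b$genes) * length(b$samples)
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("bicluster: %d genes x %d samples (%s)\n",
              length(x$genes), length(x$samples), x$direction))
  if (!is.na(x$score)) cat(sprintf("  score I = %.4g", x$score))
  if (!is.na(x$nscore)) cat(sprintf(", NI = %.4g", x$nscore))
  if (!is.na(x$score) || !is.na(x$nscore)) cat("\n")
  invisible(x)
}

#' Construct an ordered collection of biclusters
#'
#' @param biclusters A list of [bicluster()] objects.
#' @param alpha Significance level used in the extension step (or `NA`).
#' @param params Named list of run parameters recorded as provenance
#'   (cut-off, min_support, c2, L, n_random, seed, ...).
#' @return An object of class `"bicluster_set"` (a list of biclusters with
#'   provenance attributes, including `cs`, the total score, once scored).
#' @export
bicluster_set <- function(biclusters = list(), alpha = NA_real_,
                          params = list()) {
  stopifnot(is.list(biclusters))
  for (b in biclusters) {
    if (!inherits(b, "bicluster")) stop("all elements must be biclusters")
  }
  structure(biclusters, class = "bicluster_set", alpha = alpha,
            params = params, cs = NA_real_)
}

#' @export
print.bicluster_set <- function(x, ...) {
  cat(sprintf("bicluster_set: %d bicluster(s)", length(x)))
  if (!is.na(attr(x, "alpha"))) cat(sprintf(", alpha = %g", attr(x, "alpha")))
  if (!is.na(attr(x, "cs"))) cat(sprintf(", CS = %.4g", attr(x, "cs")))
  cat("\n")
  for (i in seq_along(x)) {
    b <- x[[i]]
    cat(sprintf("  [%d] %d genes x %d samples (%s)\n", i,
                length(b$genes), length(b$samples), b$direction))
  }
  invisible(x)
}

#' @export
`[.bicluster_set` <- function(x, i) {
  bicluster_set(unclass(x)[i], alpha = attr(x, "alpha"),
                params = attr(x, "params"))
}

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Write a bicluster set to a plain-text file
#'
#' One block per bicluster, blank-line separated, each line a
#' `key<TAB>value(s)` pair with keys `bicluster`, `direction`, `alpha`,
#' `genes`, `samples`, `pvalues`, `score_I`, `score_NI`. A comment header
#' records provenance (package version, run parameters, seed). Numbers are
#' printed with 17 significant digits so that [read_biclusters()] recovers
#' them exactly.
#'
#' @param result A [bicluster_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biclusters <- function(result, path) {
  stopifnot(inherits(result, "bicluster_set"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  params <- attr(result, "params")
  writeLines("# debi bicluster set", con)
  writeLines(paste0("# version: ",
                    as.character(utils::packageVersion("debi"))), con)
  writeLines(paste0("# alpha: ", fmt_num(attr(result, "alpha"))), con)
  writeLines(paste0("# cs: ", fmt_num(attr(result, "cs"))), con)
  for (key in names(params)) {
    writeLines(paste0("# ", key, ": ",
                      paste(fmt_any(params[[key]]), collapse = ",")), con)
  }
  writeLines(paste0("# n_biclusters: ", length(result)), con)
  for (i in seq_along(result)) {
    b <- result[[i]]
    writeLines("", con)
    writeLines(paste0("bicluster\t", i), con)
    writeLines(paste0("direction\t", b$direction), con)
    writeLines(paste0("alpha\t", fmt_num(attr(result, "alpha"))), con)
    writeLines(paste(c("genes", b$genes), collapse = "\t"), con)
    writeLines(paste(c("samples", b$samples), collapse = "\t"), con)
    pv <- if (is.null(b$pvalues)) rep(NA_real_, length(b$genes)) else b$pvalues
    writeLines(paste(c("pvalues", fmt_num(pv)), collapse = "\t"), con)
    writeLines(paste0("score_I\t", fmt_num(b$score)), con)
    writeLines(paste0("score_NI\t", fmt_num(b$nscore)), con)
  }
  invisible(path)
}

fmt_any <- function(x) {
  if (is.numeric(x)) fmt_num(x) else as.character(x)
}

#' Read a bicluster set written by [write_biclusters()]
#'
#' @param path Path to a bicluster text file.
#' @return A [bicluster_set()].
#' @export
read_biclusters <- function(path) {
  parse_num <- function(x) {
    x[x == "NA"] <- NA_character_
    as.numeric(x)
  }
  lines <- readLines(path, encoding = "UTF-8")
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  alpha <- NA_real_
  cs <- NA_real_
  params <- list()
  for (h in header) {
    kv <- sub("^#\\s*", "", h)
    sep <- regexpr(": ", kv, fixed = TRUE)
    if (sep < 0) next
    key <- substr(kv, 1L, sep - 1L)
    val <- substr(kv, sep + 2L, nchar(kv))
    if (key == "alpha") alpha <- parse_num(val)
    else if (key == "cs") cs <- parse_num(val)
    else if (!key %in% c("version", "n_biclusters", "debi bicluster set")) {
      params[[key]] <- val
    }
  }
  blocks <- split_blocks(body)
  bics <- lapply(seq_along(blocks), function(i) {
    kv <- parse_block(blocks[[i]], i)
    pv <- parse_num(kv$pvalues)
    bicluster(
      genes = kv$genes, samples = kv$samples, direction = kv$direction,
      pvalues = if (all(is.na(pv))) NULL else pv,
      score = parse_num(kv$score_I), nscore = parse_num(kv$score_NI)
    )
  })
  out <- bicluster_set(bics, alpha = alpha, params = params)
  attr(out, "cs") <- cs
  out
}

split_blocks <- function(body) {
  blank <- !nzchar(trimws(body))
  grp <- cumsum(blank)
  blocks <- split(body[!blank], grp[!blank])
  Filter(length, unname(blocks))
}

parse_block <- function(block, idx) {
  kv <- list()
  for (line in block) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) {
      stop("malformed bicluster block ", idx, ": line ", dQuote(line))
    }
    kv[[fields[1L]]] <- fields[-1L]
  }
  need <- c("bicluster", "direction", "genes", "samples",
            "pvalues", "score_I", "score_NI")
  missing <- setdiff(need, names(kv))
  if (length(missing)) {
    stop("bicluster block ", idx, " is missing field(s): ",
         paste(missing, collapse = ", "))
  }
  kv
}
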