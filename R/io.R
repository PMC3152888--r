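#' Read a gene x sample expression table
#'
#' Reads a delimited text table with sample identifiers in the first row and
#' gene identifiers in the first column. Cells are numeric expression values
#' (log2 ratios by default conventions of this package); empty cells are
#' recorded as missing (`NA`). Row and column order are preserved.
#'
#' The header row may or may not carry a corner label above the gene-id
#' column; both layouts are accepted.
#'
#' @param path Path to the input file.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return A numeric matrix with gene identifiers as `rownames` and sample
#'   identifiers as `colnames`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t1.5\t-0.2", "g2\t0\t2.1"), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 1L]
  if (length(lines) < 2L) {
    stop("expected a header row and at least one gene row in ", path)
  }
  ## sentinel keeps trailing empty cells, which strsplit would drop
  fields <- lapply(strsplit(paste0(lines, sep, "\\x01"), sep, fixed = TRUE),
                   function(f) f[-length(f)])
  header <- fields[[1L]]
  body <- fields[-1L]
  widths <- lengths(body)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged row ", bad + 1L, ": expected ", widths[1L],
         " fields, found ", widths[bad])
  }
  ncols <- widths[1L] - 1L
  if (ncols < 1L) stop("no sample columns found in ", path)
  if (length(header) == ncols + 1L) {
    sample_ids <- header[-1L]          # corner label present
  } else if (length(header) == ncols) {
    sample_ids <- header               # no corner label
  } else {
    stop("header has ", length(header), " fields but data rows have ",
         ncols + 1L)
  }
  gene_ids <- vapply(body, `[`, character(1L), 1L)
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  }
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) {
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "))
  }
  vals <- matrix(NA_real_, length(body), ncols,
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    empty <- !nzchar(trimws(cells)) | toupper(trimws(cells)) == "NA"
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & !empty)
    if (length(bad)) {
      stop("non-numeric value ", dQuote(cells[bad[1L]]), " at gene ",
           dQuote(gene_ids[i]), ", sample ", dQuote(sample_ids[bad[1L]]))
    }
    num[empty] <- NA_real_
    vals[i, ] <- num
  }
  vals
}

#' Write an expression matrix back to delimited text
#'
#' Inverse of [read_expression()]: writes a header of sample identifiers
#' (with a `gene` corner label) and one row per gene. Missing values are
#' written as empty cells.
#'
#' @param E Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(E, path, sep = "\t") {
  stopifnot(is.matrix(E), !is.null(rownames(E)), !is.null(colnames(E)))
  fmt <- function(x) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- ""
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(E)), collapse = sep), con)
  for (i in seq_len(nrow(E))) {
    writeLines(paste(c(rownames(E)[i], fmt(E[i, ])), collapse = sep), con)
  }
  invisible(path)
}

#' Binarize an expression matrix into a regulation indicator matrix
#'
#' Thresholds a log2-ratio expression matrix into a 0/1 matrix of c-fold
#' regulation calls: for `direction = "up"`, entry (i,j) is 1 iff
#' `E[i,j] >= log2(c)`; for `direction = "down"`, 1 iff
#' `E[i,j] <= -log2(c)`. Missing values binarize to 0 (absence of evidence
#' of regulation). Values are assumed to be log2 ratios; set
#' `linear = TRUE` to log2-transform positive linear-scale values first.
#'
#' @param E Numeric expression matrix (genes x samples, named dimensions).
#' @param c Fold-change cut-off, a number > 1 (typically 2).
#' @param direction `"up"` or `"down"`.
#' @param linear If `TRUE`, apply `log2` to `E` before thresholding.
#' @return An integer 0/1 matrix with the same dimnames, carrying
#'   attributes `direction` and `cutoff`.
#' @examples
#' E <- matrix(c(1.5, 0, -2, 0.7), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' binarize(E, c = 2, direction = "up")
#' @export
binarize <- function(E, c = 2, direction = c("up", "down"), linear = FALSE) {
  direction <- match.arg(direction)
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 1) {
    stop("fold-change cut-off `c` must be a single number > 1")
  }
  stopifnot(is.matrix(E), is.numeric(E))
  if (linear) E <- log2(E)
  thr <- log2(c)
  bits <- if (direction == "up") E >= thr else E <= -thr
  bits[is.na(bits)] <- FALSE
  B <- matrix(as.integer(bits), nrow(E), ncol(E), dimnames = dimnames(E))
  attr(B, "direction") <- direction
  attr(B, "cutoff") <- c
  B
}

#' Tag a pre-binarized 0/1 matrix for use in the pipeline
#'
#' For inputs that are already binary (for example gene-set membership
#' matrices, where a 1 marks a gene affected in a given set), this bypasses
#' thresholding entirely and only validates and tags the matrix.
#'
#' @param B A matrix containing only 0/1 (or logical) entries, with gene row
#'   names and sample column names.
#' @return An integer 0/1 matrix with `direction = "as_given"` and
#'   `cutoff = NA`.
#' @export
as_binary_matrix <- function(B) {
  stopifnot(is.matrix(B))
  vals <- as.vector(B)
  if (is.logical(vals)) vals <- as.integer(vals)
  if (!all(vals %in% c(0L, 1L))) {
    stop("matrix entries must all be 0 or 1")
  }
  out <- matrix(as.integer(vals), nrow(B), ncol(B), dimnames = dimnames(B))
  attr(out, "direction") <- "as_given"
  attr(out, "cutoff") <- NA_real_
  out
}

bm_direction <- function(B) {
  d <- attr(B, "direction")
  if (is.null(d)) "as_given" else d
}
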