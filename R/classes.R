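#' Construct a count matrix
#'
#' Bundles an integer gene-by-sample matrix of uniquely mapped read counts
#' with the per-sample library sizes (total mapped reads) needed for RPKM
#' normalization. Counts are validated to be non-negative whole numbers and
#' per-sample count totals may not exceed the corresponding library size.
#'
#' @param counts Numeric matrix of non-negative whole-number read counts with
#'   unique, non-empty rownames (gene IDs) and colnames (sample names).
#' @param library_sizes Named numeric vector of total mapped reads per sample,
#'   in the column order of `counts`. Defaults to the column sums, which is
#'   the right fallback when every mapped read hits an annotated gene.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `library_sizes` (named numeric vector).
#' @examples
#' m <- matrix(c(10L, 0L, 25L, 3L), 2, 2,
#'             dimnames = list(c("AT1G00010", "AT1G00020"), c("IM", "F12")))
#' cm <- count_matrix(m, c(IM = 1e6, F12 = 1e6))
#' cm
#' @export
count_matrix <- function(counts, library_sizes = colSums(counts)) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("'counts' must have unique rownames (gene IDs)")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("'counts' must have unique colnames (sample names)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != floor(counts))) stop("counts must be whole numbers")
  if (length(library_sizes) != ncol(counts))
    stop("'library_sizes' must have one entry per sample")
  if (is.null(names(library_sizes))) {
    names(library_sizes) <- colnames(counts)
  } else if (!identical(sort(names(library_sizes)), sort(colnames(counts)))) {
    stop("names of 'library_sizes' must match sample names")
  }
  library_sizes <- library_sizes[colnames(counts)]
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  over <- colSums(counts) > library_sizes
  if (any(over))
    stop("per-sample count totals exceed library sizes for: ",
         paste(colnames(counts)[over], collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("library sizes: ",
      paste(names(x$library_sizes), format(x$library_sizes, big.mark = ","),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Sample names of a count or expression matrix
#' @param x A `count_matrix` or `expression_matrix`.
#' @return Character vector of sample names.
#' @export
sample_names <- function(x) UseMethod("sample_names")

#' @export
sample_names.count_matrix <- function(x) colnames(x$counts)

#' @export
sample_names.expression_matrix <- function(x) colnames(x$values)

#' Gene IDs of a count or expression matrix
#' @param x A `count_matrix` or `expression_matrix`.
#' @return Character vector of gene identifiers.
#' @export
gene_ids <- function(x) UseMethod("gene_ids")

#' @export
gene_ids.count_matrix <- function(x) rownames(x$counts)

#' @export
gene_ids.expression_matrix <- function(x) rownames(x$values)

#' Construct an expression matrix
#'
#' A gene-by-sample matrix of normalized expression values tagged with its
#' scale: `"rpkm"` for reads per kilobase of transcript per million mapped
#' reads, or `"log2"` for log2-transformed RPKM.
#'
#' @param values Numeric matrix with gene rownames and sample colnames.
#' @param scale Either `"rpkm"` or `"log2"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `scale`.
#' @export
expression_matrix <- function(values, scale = c("rpkm", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene rownames and sample colnames")
  if (scale == "rpkm" && any(values < 0))
    stop("rpkm-scale values must be non-negative")
  structure(list(values = values, scale = scale), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (", x$scale, "): ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
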