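#' RPKM normalization of a read-count matrix
#'
#' Converts raw uniquely mapped read counts to reads per kilobase of
#' transcript per million mapped reads:
#' `RPKM = 1e9 * C / (N * L)`, where `C` is the count for a gene in a
#' sample, `N` the sample's total mapped reads and `L` the cDNA length (bp)
#' of the gene's longest splice variant.
#'
#' @param counts A [count_matrix()].
#' @param annotation Gene annotation data.frame with `gene_id` and
#'   `length_bp` columns; every gene in `counts` must be present.
#' @return An [expression_matrix()] on the `"rpkm"` scale with the same
#'   dimensions as `counts`.
#' @examples
#' m <- matrix(10L, 1, 1, dimnames = list("g1", "s1"))
#' cm <- count_matrix(m, c(s1 = 1e6))
#' ann <- data.frame(gene_id = "g1", length_bp = 1000L)
#' rpkm(cm, ann)$values   # 10
#' @export
rpkm <- function(counts, annotation) {
  if (!inherits(counts, "count_matrix"))
    stop("'counts' must be a count_matrix")
  ids <- gene_ids(counts)
  hit <- match(ids, annotation$gene_id)
  if (anyNA(hit))
    stop("no gene model (length) for: ",
         paste(ids[is.na(hit)], collapse = ", "))
  L <- annotation$length_bp[hit]
  if (any(L < 1)) stop("gene lengths must be >= 1 bp")
  N <- counts$library_sizes
  vals <- 1e9 * counts$counts /
    (rep(N, each = length(ids)) * L)
  dimnames(vals) <- dimnames(counts$counts)
  expression_matrix(vals, "rpkm")
}

#' Log2-transform an RPKM matrix
#'
#' Applies `log2(rpkm + pseudocount)` elementwise. The pseudocount (default
#' 1) keeps zero-count genes finite while preserving the ordering of
#' expression values.
#'
#' @param expr An [expression_matrix()] on the `"rpkm"` scale.
#' @param pseudocount Positive value added before taking logs.
#' @return An [expression_matrix()] on the `"log2"` scale; the pseudocount
#'   used is recorded in the `pseudocount` element.
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  if (!inherits(expr, "expression_matrix"))
    stop("'expr' must be an expression_matrix")
  if (expr$scale != "rpkm")
    stop("input is already on the log2 scale; expected an rpkm-scale matrix")
  if (pseudocount <= 0) stop("'pseudocount' must be positive")
  out <- expression_matrix(log2(expr$values + pseudocount), "log2")
  out$pseudocount <- pseudocount
  out
}

#' Call expressed genes by a read-count threshold
#'
#' A gene is called expressed in a sample when at least `min_reads` reads
#' map to it (default 10). Also reports the union across samples — the
#' set of genes expressed anywhere in the series.
#'
#' @param counts A [count_matrix()].
#' @param min_reads Minimum read count to call a gene expressed (>= 1).
#' @return List with `per_sample` (named list of gene-ID vectors) and
#'   `union` (character vector).
#' @export
call_expressed <- function(counts, min_reads = 10) {
  if (!inherits(counts, "count_matrix"))
    stop("'counts' must be a count_matrix")
  if (min_reads < 1) stop("'min_reads' must be >= 1")
  ids <- gene_ids(counts)
  per_sample <- lapply(seq_along(sample_names(counts)), function(j)
    ids[counts$counts[, j] >= min_reads])
  names(per_sample) <- sample_names(counts)
  union_set <- ids[rowSums(counts$counts >= min_reads) > 0]
  list(per_sample = per_sample, union = union_set)
}

#' Align a count matrix to an annotation
#'
#' Genes present in the annotation but absent from the count matrix are
#' appended with zero counts (with a message listing how many), so that
#' downstream set comparisons against annotation-derived universes are
#' well defined. Genes in the counts but not the annotation are an error
#' in [rpkm()], not here.
#'
#' @param counts A [count_matrix()].
#' @param annotation Annotation data.frame with `gene_id`.
#' @return A [count_matrix()] covering every annotated gene.
#' @export
align_counts <- function(counts, annotation) {
  if (!inherits(counts, "count_matrix"))
    stop("'counts' must be a count_matrix")
  missing <- setdiff(annotation$gene_id, gene_ids(counts))
  if (length(missing) == 0) return(counts)
  message(length(missing),
          " annotated gene(s) absent from counts; treated as count 0")
  pad <- matrix(0L, length(missing), ncol(counts$counts),
                dimnames = list(missing, sample_names(counts)))
  count_matrix(rbind(counts$counts, pad), counts$library_sizes)
}
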