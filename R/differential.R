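#' Fisher's exact test for differential expression between two libraries
#'
#' Tests whether a gene's read count differs between two samples beyond
#' sampling noise, via a two-sided Fisher's exact test on the 2x2 table
#' `[[count_a, lib_a - count_a], [count_b, lib_b - count_b]]`. Vectorized
#' over genes. Note the caveat: with a single library per condition the
#' test captures only counting (binomial) noise, so it is anticonservative
#' when counts are overdispersed across conditions.
#'
#' @param count_a,count_b Non-negative integer read counts (vectors OK).
#' @param lib_a,lib_b Total mapped reads of the two libraries.
#' @return Vector of two-sided P-values.
#' @examples
#' fisher_deg(5, 5, 1e6, 1e6)   # identical rows -> 1
#' @export
fisher_deg <- function(count_a, count_b, lib_a, lib_b) {
  k <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, k)
  count_b <- rep_len(count_b, k)
  if (any(count_a < 0) || any(count_b < 0))
    stop("counts must be non-negative")
  if (any(count_a > lib_a) || any(count_b > lib_b))
    stop("counts cannot exceed library sizes")
  vapply(seq_len(k), function(i)
    fisher_exact_p(count_a[i], lib_a - count_a[i],
                   count_b[i], lib_b - count_b[i]),
    numeric(1))
}

#' Fold change between two expression values
#'
#' Pseudocount-stabilized ratio `(a + pseudocount) / (b + pseudocount)`.
#' With the default pseudocount of 1 RPKM, a gene silent in both samples
#' has fold change 1 and no ratio is ever infinite.
#'
#' @param rpkm_a,rpkm_b Non-negative expression values (vectors OK).
#' @param pseudocount Non-negative stabilizer added to both values.
#' @return Fold change(s) of `a` over `b`.
#' @export
fold_change <- function(rpkm_a, rpkm_b, pseudocount = 1) {
  if (any(rpkm_a < 0) || any(rpkm_b < 0)) stop("inputs must be >= 0")
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  (rpkm_a + pseudocount) / (rpkm_b + pseudocount)
}

#' Per-gene differential-expression table for a sample pair
#'
#' Runs [fisher_deg()] for every gene between two samples and combines it
#' with the RPKM fold change. A gene is flagged as differentially expressed
#' (DEG) when `p < alpha` and `|log2 fold change| >= log2(min_fold)`;
#' the default `min_fold = 1` imposes no fold filter, matching a raw
#' `P < 0.01` call.
#'
#' @param counts A [count_matrix()].
#' @param annotation Annotation with `gene_id`, `length_bp` (for RPKM).
#' @param pair Character vector of two sample names `c(a, b)`.
#' @param alpha Significance level for the Fisher test.
#' @param min_fold Minimum fold change (>= 1) for the DEG flag.
#' @param pseudocount RPKM pseudocount used in the fold change.
#' @param p_adjust If `TRUE`, apply Benjamini-Hochberg correction and test
#'   the adjusted values against `alpha` instead of the raw P-values.
#' @return data.frame with one row per gene: `gene_id`, `sample_a`,
#'   `sample_b`, `count_a`, `count_b`, `p_value`, `log2_fold_change`,
#'   `deg` and `direction` (`up_in_a`, `up_in_b` or `none`).
#' @export
deg_table <- function(counts, annotation, pair, alpha = 0.01, min_fold = 1,
                      pseudocount = 1, p_adjust = FALSE) {
  if (length(pair) != 2 || !all(pair %in% sample_names(counts)))
    stop("'pair' must name two samples of the count matrix")
  if (min_fold < 1) stop("'min_fold' must be >= 1")
  a <- pair[1]; b <- pair[2]
  ca <- counts$counts[, a]
  cb <- counts$counts[, b]
  p <- fisher_deg(ca, cb, counts$library_sizes[[a]],
                  counts$library_sizes[[b]])
  expr <- rpkm(counts, annotation)
  lfc <- log2(fold_change(expr$values[, a], expr$values[, b], pseudocount))
  p_eff <- if (p_adjust) stats::p.adjust(p, "BH") else p
  deg <- p_eff < alpha & abs(lfc) >= log2(min_fold)
  direction <- ifelse(!deg | lfc == 0, "none",
                      ifelse(lfc > 0, "up_in_a", "up_in_b"))
  data.frame(gene_id = gene_ids(counts), sample_a = a, sample_b = b,
             count_a = as.integer(ca), count_b = as.integer(cb),
             p_value = p, log2_fold_change = lfc, deg = deg,
             direction = direction, stringsAsFactors = FALSE)
}

#' Stage-specific genes at a fold threshold
#'
#' A gene is specific to `stage` when its RPKM fold change over EVERY other
#' sample exceeds `fold` and (by default) its pairwise Fisher test against
#' every other sample is significant at `alpha`. Set
#' `require_significance = FALSE` for a fold-only call, useful for
#' sensitivity analysis of the conjunction.
#'
#' @param counts A [count_matrix()].
#' @param annotation Annotation with `gene_id`, `length_bp`.
#' @param stage Sample name the genes should be specific to.
#' @param fold Fold-change threshold (>= 1); the comparison is strict
#'   (`> fold`).
#' @param alpha Significance level for the pairwise Fisher tests.
#' @param pseudocount RPKM pseudocount for the fold change.
#' @param require_significance Require pairwise Fisher significance in
#'   addition to the fold condition.
#' @return Character vector of stage-specific gene IDs.
#' @export
stage_specific <- function(counts, annotation, stage, fold = 4,
                           alpha = 0.01, pseudocount = 1,
                           require_significance = TRUE) {
  samples <- sample_names(counts)
  if (!stage %in% samples) stop("unknown stage: ", stage)
  if (fold < 1) stop("'fold' must be >= 1")
  others <- setdiff(samples, stage)
  if (length(others) == 0) stop("need at least two samples")
  expr <- rpkm(counts, annotation)
  keep <- rep(TRUE, nrow(counts$counts))
  for (o in others) {
    fc <- fold_change(expr$values[, stage], expr$values[, o], pseudocount)
    ok <- fc > fold
    if (require_significance) {
      idx <- which(keep & ok)   # only test genes still in the running
      sig <- rep(FALSE, length(ok))
      if (length(idx))
        sig[idx] <- fisher_deg(counts$counts[idx, stage],
                               counts$counts[idx, o],
                               counts$library_sizes[[stage]],
                               counts$library_sizes[[o]]) < alpha
      ok <- ok & sig
    }
    keep <- keep & ok
  }
  gene_ids(counts)[keep]
}

#' Stage-specific gene counts across fold thresholds
#'
#' Tabulates [stage_specific()] for every sample at each fold threshold,
#' producing a fold-by-stage count table. Columns are monotone
#' non-increasing down the rows because the specific sets are nested as
#' the threshold rises.
#'
#' @inheritParams stage_specific
#' @param folds Numeric vector of fold thresholds.
#' @return data.frame with a `fold` column and one count column per sample.
#' @export
stage_specific_table <- function(counts, annotation, folds = c(1, 2, 4, 8),
                                 alpha = 0.01, pseudocount = 1,
                                 require_significance = TRUE) {
  samples <- sample_names(counts)
  out <- data.frame(fold = folds)
  for (s in samples)
    out[[s]] <- vapply(folds, function(f)
      length(stage_specific(counts, annotation, s, f, alpha, pseudocount,
                            require_significance)), numeric(1))
  out
}

#' Group genes by the stage of their maximal expression
#'
#' Partitions a gene set by the sample in which each gene's expression is
#' highest — the grouping behind developmental-stage classes such as a
#' D1/D2/D3 split of differentially expressed transcription factors. Exact
#' ties are broken in favour of the earliest sample in column order, with a
#' message reporting how many ties were broken.
#'
#' @param expr An [expression_matrix()] (either scale; the grouping is
#'   invariant to monotone transforms).
#' @param genes Gene IDs to partition; defaults to all rows.
#' @return Named list, one element per sample (possibly empty), whose
#'   elements partition `genes`.
#' @export
max_stage_groups <- function(expr, genes = NULL) {
  if (!inherits(expr, "expression_matrix"))
    stop("'expr' must be an expression_matrix")
  if (is.null(genes)) genes <- rownames(expr$values)
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing))
    stop("genes not in matrix: ", paste(missing, collapse = ", "))
  m <- expr$values[genes, , drop = FALSE]
  top <- max.col(m, ties.method = "first")
  n_tied <- sum(rowSums(m == m[cbind(seq_len(nrow(m)), top)]) > 1)
  if (n_tied > 0)
    message(n_tied, " tie(s) broken in favour of the earliest stage")
  stages <- colnames(m)
  split(genes, factor(stages[top], levels = stages))
}
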