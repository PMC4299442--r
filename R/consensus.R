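#' Tiling-array background threshold from platform-specific genes
#'
#' Genes that carry a tiling probe but are detected neither by RNA-seq nor
#' by ESTs are, as a population, dominated by untranscribed loci
#' (transposons, pseudogenes) plus genes expressed at very low levels.
#' Their mean tiling intensity therefore estimates the array's effective
#' background and becomes the expressed/unexpressed threshold for
#' [call_tiling_expressed()]. The gene-type breakdown of the
#' platform-specific set is reported alongside.
#'
#' @param evidence Platform-evidence data.frame with `gene_id`,
#'   `probe_present`, `tiling_intensity` and `gene_type`.
#' @param rnaseq_set,est_set Gene IDs detected by RNA-seq / supported by at
#'   least one EST.
#' @return List with `threshold` (mean intensity of the specific genes),
#'   `specific_genes` (their IDs) and `breakdown` (named counts:
#'   transposon, pseudogene, other).
#' @export
tiling_background <- function(evidence, rnaseq_set, est_set) {
  if (nrow(evidence) == 0) stop("'evidence' is empty")
  spec <- evidence$probe_present &
    !(evidence$gene_id %in% rnaseq_set) &
    !(evidence$gene_id %in% est_set)
  if (!any(spec))
    stop("no tiling-specific genes; background threshold is undefined")
  ids <- evidence$gene_id[spec]
  intensity <- evidence$tiling_intensity[spec]
  types <- evidence$gene_type[spec]
  breakdown <- c(transposon = sum(types == "transposon"),
                 pseudogene = sum(types == "pseudogene"),
                 other = sum(!types %in% c("transposon", "pseudogene")))
  list(threshold = mean(intensity), specific_genes = ids,
       breakdown = breakdown)
}

#' Call genes expressed on the tiling array
#'
#' Probe-covered genes whose tiling intensity strictly exceeds the
#' background threshold (typically from [tiling_background()]).
#'
#' @param evidence Platform-evidence data.frame.
#' @param threshold Finite intensity threshold (log2 scale).
#' @return Character vector of gene IDs.
#' @export
call_tiling_expressed <- function(evidence, threshold) {
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  hit <- evidence$probe_present & !is.na(evidence$tiling_intensity) &
    evidence$tiling_intensity > threshold
  evidence$gene_id[hit]
}

#' Call genes expressed on the microarray
#'
#' Probed genes whose microarray intensity strictly exceeds the fixed
#' background value, 5 on the log2 scale by default. Genes without a
#' microarray probe are excluded regardless of expression — this is
#' exactly the blind spot that deeper RNA-seq fills in.
#'
#' @param evidence Platform-evidence data.frame with
#'   `microarray_intensity` (`NA` when unprobed).
#' @param background Log2 intensity background (default 5).
#' @return Character vector of gene IDs.
#' @export
call_microarray_expressed <- function(evidence, background = 5) {
  hit <- !is.na(evidence$microarray_intensity) &
    evidence$microarray_intensity > background
  evidence$gene_id[hit]
}

#' Three-platform Venn partition of detected genes
#'
#' Splits the union of RNA-seq-, EST- and tiling-detected genes into the
#' seven disjoint Venn regions and extracts the reliable set: genes
#' detected by at least two platforms.
#'
#' @param rnaseq,est,tiling Gene-ID character vectors.
#' @return Object of class `venn_partition`: list with `regions` (named
#'   list of 7 gene-ID vectors: `rnaseq_only`, `est_only`, `tiling_only`,
#'   `rnaseq_est`, `rnaseq_tiling`, `est_tiling`, `all_three`), `counts`
#'   (named integer vector over the same regions) and `reliable_set`.
#' @export
platform_venn <- function(rnaseq, est, tiling) {
  rnaseq <- unique(rnaseq); est <- unique(est); tiling <- unique(tiling)
  universe <- unique(c(rnaseq, est, tiling))
  in_r <- universe %in% rnaseq
  in_e <- universe %in% est
  in_t <- universe %in% tiling
  regions <- list(
    rnaseq_only   = universe[in_r & !in_e & !in_t],
    est_only      = universe[!in_r & in_e & !in_t],
    tiling_only   = universe[!in_r & !in_e & in_t],
    rnaseq_est    = universe[in_r & in_e & !in_t],
    rnaseq_tiling = universe[in_r & !in_e & in_t],
    est_tiling    = universe[!in_r & in_e & in_t],
    all_three     = universe[in_r & in_e & in_t])
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1)),
                 reliable_set = universe[in_r + in_e + in_t >= 2]),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition over", sum(x$counts), "detected genes\n")
  print(x$counts)
  cat("reliable (>=2 platforms):", length(x$reliable_set), "\n")
  invisible(x)
}

#' Reliably expressed gene counts from a Venn partition
#'
#' Two summaries of cross-platform support. `two_platform` counts genes
#' detected by at least two of the three platforms (triple region plus all
#' three pairwise-only regions). `rnaseq_anchored` counts the triple
#' region plus only the pairwise regions that include RNA-seq — the
#' arithmetic conventionally quoted as the "reliably expressed" floral
#' total, which credits EST/tiling co-detection only when sequencing
#' confirms it.
#'
#' @param venn A [platform_venn()] result.
#' @return List with integers `two_platform`, `rnaseq_anchored` and
#'   `rnaseq_only`.
#' @export
reliable_expressed_count <- function(venn) {
  if (!inherits(venn, "venn_partition"))
    stop("'venn' must come from platform_venn()")
  n <- venn$counts
  list(two_platform = unname(n["all_three"] + n["rnaseq_est"] +
                               n["rnaseq_tiling"] + n["est_tiling"]),
       rnaseq_anchored = unname(n["all_three"] + n["rnaseq_est"] +
                                  n["rnaseq_tiling"]),
       rnaseq_only = unname(n["rnaseq_only"]))
}
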