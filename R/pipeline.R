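#' Pipeline configuration
#'
#' Bundles inputs and thresholds for [run_pipeline()]. Inputs may be given
#' as file paths (`counts_file`, `annotation_file`, `evidence_file`) or as
#' in-memory objects (`counts`, `annotation`, `evidence`); objects win
#' when both are supplied. Threshold defaults are the conventional values
#' of this analysis style: 10 reads to call a gene expressed, Fisher
#' `P < 0.01` for differential expression, log2 microarray background of
#' 5, fold thresholds 1/2/4/8 for stage-specific detection, and RPKM
#' pseudocount 1.
#'
#' @param counts,annotation,evidence In-memory inputs (a [count_matrix()]
#'   and two data.frames), or `NULL` to read from files.
#' @param counts_file,annotation_file,evidence_file Input paths.
#' @param outdir Output directory for the pipeline artifacts.
#' @param min_reads Expressed-gene read threshold.
#' @param alpha Fisher significance level.
#' @param microarray_background Log2 microarray background.
#' @param folds Fold thresholds for stage-specific detection.
#' @param pseudocount RPKM pseudocount (fold changes and log transform).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, annotation = NULL,
                            evidence = NULL,
                            counts_file = NULL, annotation_file = NULL,
                            evidence_file = NULL,
                            outdir = tempfile("florastage_"),
                            min_reads = 10, alpha = 0.01,
                            microarray_background = 5,
                            folds = c(1, 2, 4, 8), pseudocount = 1) {
  if (is.null(counts) && is.null(counts_file))
    stop("provide 'counts' or 'counts_file'")
  if (is.null(annotation) && is.null(annotation_file))
    stop("provide 'annotation' or 'annotation_file'")
  if (min_reads < 1) stop("'min_reads' must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (any(folds < 1)) stop("'folds' must be >= 1")
  if (pseudocount <= 0) stop("'pseudocount' must be positive")
  structure(list(counts = counts, annotation = annotation,
                 evidence = evidence,
                 counts_file = counts_file,
                 annotation_file = annotation_file,
                 evidence_file = evidence_file,
                 outdir = outdir, min_reads = min_reads, alpha = alpha,
                 microarray_background = microarray_background,
                 folds = sort(folds), pseudocount = pseudocount),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes quantification, differential expression, stage-specificity,
#' cross-platform consensus (when evidence is available) and family
#' detection/enrichment on one count matrix, writing every artifact under
#' `config$outdir` plus a machine-readable `summary.json`. The pipeline is
#' deterministic: rerunning on the same inputs reproduces the summary
#' byte for byte.
#'
#' Artifacts: `rpkm.tsv`, `expressed_<sample>.txt` and
#' `expressed_union.txt`, `deg_<a>_vs_<b>.tsv` per sample pair,
#' `stage_specific_counts.tsv`, `stage_specific.tsv`, `zscores.tsv`,
#' `venn.tsv`, `consensus.txt`, `enrichment.tsv`, `summary.json`.
#'
#' @param config A [pipeline_config()].
#' @return The summary, invisibly: expressed-gene counts per sample, DEG
#'   counts per pair (split by direction), stage-specific counts per fold
#'   level, Venn region counts and consensus totals, and the top enriched
#'   families of the stage-of-maximal-expression groups.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must come from pipeline_config()")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  annotation <- run_stage("read_annotation",
    if (!is.null(config$annotation)) config$annotation
    else read_annotation(config$annotation_file))
  counts <- run_stage("read_counts",
    if (!is.null(config$counts)) config$counts
    else read_counts(config$counts_file))
  evidence <- run_stage("read_evidence",
    if (!is.null(config$evidence)) config$evidence
    else if (!is.null(config$evidence_file))
      read_evidence(config$evidence_file)
    else NULL)

  counts <- run_stage("align_counts",
                      suppressMessages(align_counts(counts, annotation)))
  samples <- sample_names(counts)

  # quantify
  expr <- run_stage("rpkm", rpkm(counts, annotation))
  lexpr <- run_stage("log2_transform",
                     log2_transform(expr, config$pseudocount))
  write_tsv(data.frame(gene_id = gene_ids(counts), expr$values,
                       check.names = FALSE),
            file.path(config$outdir, "rpkm.tsv"))
  expressed <- run_stage("call_expressed",
                         call_expressed(counts, config$min_reads))
  for (s in samples)
    write_gene_set(expressed$per_sample[[s]],
                   file.path(config$outdir, paste0("expressed_", s, ".txt")))
  write_gene_set(expressed$union,
                 file.path(config$outdir, "expressed_union.txt"))

  # differential
  pairs <- utils::combn(samples, 2, simplify = FALSE)
  deg_counts <- list()
  for (p in pairs) {
    tab <- run_stage(paste0("deg_table ", p[1], " vs ", p[2]),
                     deg_table(counts, annotation, p, config$alpha,
                               pseudocount = config$pseudocount))
    write_tsv(tab, file.path(config$outdir,
                             paste0("deg_", p[1], "_vs_", p[2], ".tsv")))
    deg_counts[[paste(p, collapse = "_vs_")]] <-
      list(up_in_a = sum(tab$direction == "up_in_a"),
           up_in_b = sum(tab$direction == "up_in_b"))
  }
  spec_tab <- run_stage("stage_specific_table",
                        stage_specific_table(counts, annotation,
                                             config$folds, config$alpha,
                                             config$pseudocount))
  write_tsv(spec_tab, file.path(config$outdir, "stage_specific_counts.tsv"))
  spec_sets <- lapply(samples, function(s)
    run_stage("stage_specific",
              stage_specific(counts, annotation, s, min(config$folds),
                             config$alpha, config$pseudocount)))
  names(spec_sets) <- samples
  spec_rows <- do.call(rbind, lapply(samples, function(s) {
    genes <- spec_sets[[s]]
    if (length(genes) == 0) return(NULL)
    # highest fold level each gene still passes
    best <- rep(min(config$folds), length(genes))
    for (f in sort(config$folds)) {
      pass <- genes %in% stage_specific(counts, annotation, s, f,
                                        config$alpha, config$pseudocount)
      best[pass] <- f
    }
    data.frame(gene_id = genes, stage = s, max_fold_passed = best,
               stringsAsFactors = FALSE)
  }))
  if (is.null(spec_rows))
    spec_rows <- data.frame(gene_id = character(0), stage = character(0),
                            max_fold_passed = numeric(0))
  write_tsv(spec_rows, file.path(config$outdir, "stage_specific.tsv"))

  # specificity
  z <- run_stage("zscores", zscores(lexpr))
  write_tsv(data.frame(gene_id = rownames(z$z), z$z, mu = z$mu,
                       sigma = z$sigma, degenerate = z$degenerate,
                       check.names = FALSE),
            file.path(config$outdir, "zscores.tsv"))

  # consensus (requires platform evidence)
  venn_counts <- NULL
  consensus <- NULL
  if (!is.null(evidence)) {
    est_set <- evidence$gene_id[evidence$est_supported]
    bg <- run_stage("tiling_background",
                    tiling_background(evidence, expressed$union, est_set))
    tiling_set <- run_stage("call_tiling_expressed",
                            call_tiling_expressed(evidence, bg$threshold))
    venn <- run_stage("platform_venn",
                      platform_venn(expressed$union, est_set, tiling_set))
    consensus <- run_stage("reliable_expressed_count",
                           reliable_expressed_count(venn))
    venn_counts <- as.list(venn$counts)
    write_tsv(data.frame(region = names(venn$counts),
                         n = unname(venn$counts),
                         genes = vapply(venn$regions, paste,
                                        character(1), collapse = ",")),
              file.path(config$outdir, "venn.tsv"))
    writeLines(c(paste0("tiling_background_threshold\t", bg$threshold),
                 paste0("two_platform\t", consensus$two_platform),
                 paste0("rnaseq_anchored\t", consensus$rnaseq_anchored),
                 paste0("rnaseq_only\t", consensus$rnaseq_only)),
               file.path(config$outdir, "consensus.txt"))
    consensus$tiling_background_threshold <- bg$threshold
  }

  # enrichment: families over-represented among union-expressed genes,
  # and detection table for genes the microarray misses
  enrich <- run_stage("family_enrichment",
                      family_enrichment(expressed$union, annotation))
  write_tsv(enrich, file.path(config$outdir, "enrichment.tsv"))
  top_families <- utils::head(enrich$family, 5)
  missed_table <- NULL
  if (!is.null(evidence) && !all(is.na(evidence$microarray_intensity))) {
    ma_set <- call_microarray_expressed(evidence,
                                        config$microarray_background)
    missed <- setdiff(expressed$union, ma_set)
    missed_table <- run_stage("family_detection_table",
                              family_detection_table(missed, annotation))
    write_tsv(missed_table,
              file.path(config$outdir, "microarray_missed_families.tsv"))
  }

  summary <- list(
    n_genes = nrow(counts$counts),
    samples = samples,
    expressed = lapply(expressed$per_sample, length),
    expressed_union = length(expressed$union),
    deg_counts = deg_counts,
    stage_specific = stats::setNames(
      lapply(seq_along(config$folds), function(i)
        as.list(spec_tab[i, samples])),
      paste0("fold_", config$folds)),
    venn = venn_counts,
    consensus = consensus,
    top_enriched_families = top_families)
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
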