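# Small in-code fixtures shared across test files.

make_counts <- function(mat, libs = NULL) {
  if (is.null(libs)) libs <- stats::setNames(rep(1e6, ncol(mat)),
                                             colnames(mat))
  count_matrix(mat, libs)
}

# one gene model per ID, constant length unless given
tiny_annotation <- function(ids, length_bp = 1000L) {
  data.frame(gene_id = ids,
             chromosome = "Chr1",
             start = seq_along(ids) * 10000L,
             end = seq_along(ids) * 10000L + length_bp - 1L,
             length_bp = rep_len(as.integer(length_bp), length(ids)),
             gene_type = "coding",
             family = NA_character_,
             tf_family = NA_character_,
             stringsAsFactors = FALSE)
}

# truth table built directly (bypassing simulate_programs) for count-model
# checks with exactly controlled means
manual_truth <- function(n, stages, mean_value, length_bp = 1000L) {
  tr <- data.frame(gene_id = sprintf("G%05d", seq_len(n)),
                   family = NA_character_, gene_type = "coding",
                   length_bp = as.integer(length_bp),
                   planted_stage = NA_character_,
                   stringsAsFactors = FALSE)
  for (s in stages) tr[[paste0("mean_", s)]] <- mean_value
  tr
}

# annotation with families of given sizes; genes are FAM_i_j plus `extra`
# unlabelled genes
family_annotation <- function(sizes, extra = 0) {
  ids <- unlist(lapply(names(sizes), function(f)
    sprintf("%s_%03d", f, seq_len(sizes[[f]]))))
  fam <- rep(names(sizes), unlist(sizes))
  if (extra > 0) {
    ids <- c(ids, sprintf("BG_%04d", seq_len(extra)))
    fam <- c(fam, rep(NA_character_, extra))
  }
  ann <- tiny_annotation(ids)
  ann$family <- fam
  ann
}
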