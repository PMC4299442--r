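# Tab-separated readers and writers. All files are UTF-8, header row,
# no quoting; gene IDs are opaque strings in the first column.

#' Write a generic tab-separated table
#' @param x data.frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' Expects a header row (`gene_id` then sample names) and integer counts.
#' An optional first line `#library_sizes<TAB>v1<TAB>v2...` carries the
#' per-sample total mapped reads in column order; without it, column sums
#' are used (the documented fallback — correct only when all mapped reads
#' hit annotated genes). Malformed input (ragged rows, non-integer cells,
#' duplicate gene IDs) is rejected with the offending line or ID named.
#'
#' @param path TSV path as written by [write_counts()].
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty counts file: ", path)
  lib_sizes <- NULL
  offset <- 0L
  if (startsWith(lines[1], "#library_sizes")) {
    fields <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
    lib_sizes <- as.numeric(fields)
    if (anyNA(lib_sizes))
      stop("line 1: malformed #library_sizes header")
    offset <- 1L
    lines <- lines[-1]
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2)
    stop("line ", offset + 1, ": need a gene_id column and >=1 sample")
  samples <- header[-1]
  body <- lines[-1]
  cells <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != length(header))
  if (length(bad))
    stop("line ", offset + 1 + bad[1], ": expected ", length(header),
         " fields, found ", lengths(cells)[bad[1]])
  ids <- vapply(cells, `[[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate gene ID(s): ", paste(unique(dup), collapse = ", "))
  raw <- unlist(lapply(cells, `[`, -1), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(raw))
  bad_cell <- which(is.na(vals) | vals != floor(vals))
  if (length(bad_cell)) {
    line_no <- offset + 1 + ceiling(bad_cell[1] / length(samples))
    stop("line ", line_no, ": non-integer count '",
         raw[bad_cell[1]], "'")
  }
  m <- matrix(as.integer(vals), nrow = length(ids), byrow = TRUE,
              dimnames = list(ids, samples))
  if (is.null(lib_sizes)) {
    count_matrix(m)
  } else {
    if (length(lib_sizes) != length(samples))
      stop("#library_sizes carries ", length(lib_sizes),
           " values for ", length(samples), " samples")
    count_matrix(m, stats::setNames(lib_sizes, samples))
  }
}

#' Write a count matrix to TSV
#'
#' Emits a `#library_sizes` line, a header row, then one row per gene.
#' Round-trips through [read_counts()].
#'
#' @param counts A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  if (!inherits(counts, "count_matrix"))
    stop("'counts' must be a count_matrix")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("#library_sizes",
                     format(counts$library_sizes, scientific = FALSE,
                            trim = TRUE)), collapse = "\t"), con)
  writeLines(paste(c("gene_id", sample_names(counts)), collapse = "\t"), con)
  writeLines(paste(gene_ids(counts),
                   apply(counts$counts, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a gene annotation table from TSV
#' @param path TSV with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `length_bp`, `gene_type`, `family`, `tf_family` (empty = `NA`).
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                           quote = "", fileEncoding = "UTF-8")
  required <- c("gene_id", "length_bp")
  missing <- setdiff(required, names(ann))
  if (length(missing))
    stop("annotation lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene ID(s) in annotation: ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
  for (col in intersect(c("gene_id", "chromosome", "gene_type", "family",
                          "tf_family"), names(ann)))
    ann[[col]] <- as.character(ann[[col]])   # all-NA columns parse as logical
  ann
}

#' Write a gene annotation table to TSV
#' @param annotation data.frame as from [simulate_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) write_tsv(annotation, path)

#' Read a platform-evidence table from TSV
#' @param path TSV with columns `gene_id`, `gene_type`, `est_supported`,
#'   `probe_present`, `tiling_intensity`, `microarray_intensity`.
#' @return data.frame with logical flag columns.
#' @export
read_evidence <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                          quote = "", fileEncoding = "UTF-8")
  required <- c("gene_id", "est_supported", "probe_present",
                "tiling_intensity")
  missing <- setdiff(required, names(ev))
  if (length(missing))
    stop("evidence lacks column(s): ", paste(missing, collapse = ", "))
  for (col in c("est_supported", "probe_present"))
    ev[[col]] <- as.logical(ev[[col]])
  ev
}

#' Read a gene set (one ID per line)
#' @param path Plain-text file, one gene ID per line; blanks ignored.
#' @return Character vector of gene IDs.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8"))
  x[nzchar(x)]
}

#' Write a gene set (one ID per line)
#' @param genes Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path, useBytes = FALSE)
  invisible(path)
}

#' Read gene families from a GMT file
#'
#' Standard tab-separated gene-set format: set name, description, then
#' member gene IDs.
#'
#' @param path GMT path.
#' @return Named list, set name -> character vector of gene IDs.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("line ", short[1], ": GMT rows need name, description, >=1 gene")
  stats::setNames(lapply(fields, `[`, -(1:2)),
                  vapply(fields, `[[`, character(1), 1))
}

#' Convert GMT-style family sets to annotation family labels
#'
#' Merges a family->genes list into an annotation's `family` column
#' (`;`-joined for genes in several families), for use with the
#' enrichment functions.
#'
#' @param sets Named list as from [read_gmt()].
#' @param annotation Annotation data.frame with `gene_id`.
#' @return The annotation with its `family` column replaced.
#' @export
apply_family_sets <- function(sets, annotation) {
  fam <- rep(NA_character_, nrow(annotation))
  for (nm in names(sets)) {
    hit <- annotation$gene_id %in% sets[[nm]]
    fam[hit] <- ifelse(is.na(fam[hit]), nm, paste(fam[hit], nm, sep = ";"))
  }
  annotation$family <- fam
  annotation
}
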