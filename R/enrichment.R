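round_half_up <- function(x, digits = 2) {
  # printed tables round halves up; base round() rounds halves to even
  floor(x * 10^digits + 0.5) / 10^digits
}

# family label column -> named list family -> member gene IDs.
# A gene may carry several ';'-separated families (protein-domain
# annotations are many-to-many) and then counts once in each.
family_members <- function(annotation) {
  fam <- annotation$family
  has <- !is.na(fam) & fam != ""
  if (!any(has)) return(list())
  parts <- strsplit(fam[has], ";", fixed = TRUE)
  split(rep(annotation$gene_id[has], lengths(parts)),
        trimws(unlist(parts)))
}

#' Per-family detection table for a gene set
#'
#' For every gene family in the annotation, counts the annotated members
#' (`total`), the members inside `gene_set` (`in_set`) and the detected
#' fraction (`percent`, rounded half-up to 2 decimals) — the layout of
#' printed family-detection tables. Rows can be filtered by minimum family
#' size and minimum fraction, and are sorted by fraction (descending) then
#' family name.
#'
#' @param gene_set Character vector of gene IDs.
#' @param annotation Annotation data.frame with `gene_id` and `family`
#'   (`;`-separated for multi-domain genes, `NA` for none).
#' @param min_percent Keep families with `percent >= min_percent`.
#' @param min_total Keep families with at least this many members.
#' @return data.frame with columns `family`, `total`, `in_set`, `percent`.
#' @export
family_detection_table <- function(gene_set, annotation, min_percent = 0,
                                   min_total = 1) {
  fams <- family_members(annotation)
  if (length(fams) == 0)
    return(data.frame(family = character(0), total = integer(0),
                      in_set = integer(0), percent = numeric(0)))
  total <- vapply(fams, length, integer(1))
  in_set <- vapply(fams, function(g) sum(g %in% gene_set), integer(1))
  percent <- round_half_up(in_set / total, 2)
  out <- data.frame(family = names(fams), total = unname(total),
                    in_set = unname(in_set), percent = unname(percent),
                    stringsAsFactors = FALSE)
  out <- out[out$total >= min_total & out$percent >= min_percent, ,
             drop = FALSE]
  out <- out[order(-out$percent, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher-exact family enrichment within a gene set
#'
#' Tests, family by family, whether membership in `gene_set` is associated
#' with carrying the family label, against a universe of genes. The 2x2
#' table per family is `[[in_set, set_rest], [out_set, universe_rest]]`
#' and the P-value is the two-sided Fisher's exact test. No multiplicity
#' correction is applied by default (printed enrichment tables typically
#' show raw P); set `p_adjust = TRUE` for Benjamini-Hochberg values in an
#' extra column.
#'
#' @param gene_set Character vector of gene IDs, a subset of `universe`.
#' @param annotation Annotation with `gene_id` and `family`.
#' @param universe Universe of gene IDs the set was drawn from; defaults
#'   to all annotated genes. This is an explicit parameter because
#'   enrichment P-values are only meaningful relative to a stated
#'   universe.
#' @param min_total Keep families with at least this many members in the
#'   universe.
#' @param p_adjust Add a BH-adjusted `p_adj` column.
#' @return data.frame sorted by `p_value`: `family`, `total`, `in_set`,
#'   `percent`, `p_value` (and `p_adj` if requested).
#' @export
family_enrichment <- function(gene_set, annotation,
                              universe = annotation$gene_id,
                              min_total = 1, p_adjust = FALSE) {
  universe <- unique(universe)
  outside <- setdiff(gene_set, universe)
  if (length(outside))
    stop("gene_set members outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  gene_set <- unique(gene_set)
  fams <- family_members(annotation)
  fams <- lapply(fams, intersect, universe)
  fams <- fams[vapply(fams, length, integer(1)) >= min_total]
  n_set <- length(gene_set)
  n_uni <- length(universe)
  rows <- lapply(names(fams), function(f) {
    g <- fams[[f]]
    total <- length(g)
    a <- sum(g %in% gene_set)
    b <- n_set - a
    c_ <- total - a
    d <- n_uni - n_set - c_
    if (min(a, b, c_, d) < 0)
      stop("inconsistent inputs for family ", f, ": negative table cell")
    data.frame(family = f, total = total, in_set = a,
               percent = round_half_up(a / total, 2),
               p_value = fisher_exact_p(a, b, c_, d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    return(data.frame(family = character(0), total = integer(0),
                      in_set = integer(0), percent = numeric(0),
                      p_value = numeric(0)))
  if (p_adjust) out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significance of the overlap between two gene sets
#'
#' Counts the overlap of two gene sets and tests it against independent
#' draws from a universe of `universe_size` genes with a two-sided
#' Fisher's exact test — the standard check that, e.g., a DEG set overlaps
#' a set of ChIP-seq target genes more than chance would allow.
#'
#' @param set_a,set_b Character vectors of gene IDs.
#' @param universe_size Number of genes in the universe; must be at least
#'   the size of the union.
#' @return List with `overlap` (integer) and `p_value`.
#' @export
set_overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  ov <- length(intersect(set_a, set_b))
  union_n <- length(set_a) + length(set_b) - ov
  if (universe_size < union_n)
    stop("universe_size (", universe_size,
         ") smaller than the union of the sets (", union_n, ")")
  a <- ov
  b <- length(set_a) - ov
  c_ <- length(set_b) - ov
  d <- universe_size - length(set_a) - length(set_b) + ov
  list(overlap = ov, p_value = fisher_exact_p(a, b, c_, d))
}

#' Detect tandem arrays of a gene family
#'
#' Scans the chromosome-ordered gene list for maximal runs of genes from
#' one family, allowing up to `max_intervening` non-family genes between
#' consecutive members and, optionally, capping the genomic distance
#' between them. Tandemly duplicated families show up as arrays of two or
#' more adjacent members.
#'
#' @param annotation Annotation with `gene_id`, `chromosome`, `start`,
#'   `end` and `family`.
#' @param family Family name to scan for.
#' @param max_intervening Maximum number of non-family genes tolerated
#'   between consecutive array members (default 1).
#' @param max_distance_bp Optional cap on the gap (bp) between the end of
#'   one member and the start of the next.
#' @return data.frame with one row per array: `family`, `chromosome`,
#'   `n_members`, `span_start`, `span_end` and `members` (comma-separated
#'   gene IDs in chromosomal order).
#' @export
detect_tandem_arrays <- function(annotation, family, max_intervening = 1,
                                 max_distance_bp = NULL) {
  if (max_intervening < 0) stop("'max_intervening' must be >= 0")
  empty <- data.frame(family = character(0), chromosome = character(0),
                      n_members = integer(0), span_start = integer(0),
                      span_end = integer(0), members = character(0))
  ord <- annotation[order(annotation$chromosome, annotation$start), ,
                    drop = FALSE]
  fam_list <- strsplit(ifelse(is.na(ord$family), "", ord$family), ";",
                       fixed = TRUE)
  is_fam <- vapply(fam_list, function(f) family %in% trimws(f), logical(1))
  arrays <- list()
  for (ch in unique(ord$chromosome)) {
    on_chr <- which(ord$chromosome == ch)
    hits <- on_chr[is_fam[on_chr]]
    if (length(hits) == 0) next
    rank <- match(hits, on_chr)
    gap_ok <- diff(rank) - 1 <= max_intervening
    if (!is.null(max_distance_bp) && length(hits) > 1) {
      dist <- ord$start[hits[-1]] - ord$end[hits[-length(hits)]]
      gap_ok <- gap_ok & dist <= max_distance_bp
    }
    run_id <- cumsum(c(0, !gap_ok))
    for (members in split(hits, run_id)) {
      if (length(members) < 2) next
      arrays[[length(arrays) + 1]] <- data.frame(
        family = family, chromosome = ch,
        n_members = length(members),
        span_start = ord$start[members[1]],
        span_end = ord$end[members[length(members)]],
        members = paste(ord$gene_id[members], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(arrays) == 0) return(empty)
  do.call(rbind, c(arrays, list(make.row.names = FALSE)))
}
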