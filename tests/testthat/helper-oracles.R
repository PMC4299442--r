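# Independent oracles, deliberately built on different primitives than the
# implementation (lchoose enumeration instead of dhyper; per-gene tallies
# instead of set algebra).

# Exhaustive two-sided Fisher P: enumerate every table with the observed
# margins via log-binomial coefficients and sum the probabilities of all
# tables no more likely than the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  if (m + n == 0) return(1)
  x <- max(0, k - n):min(k, m)
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p <- exp(logp)
  p_obs <- p[x == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Per-gene membership tally of the 7 Venn regions.
oracle_venn_counts <- function(rnaseq, est, tiling) {
  universe <- unique(c(rnaseq, est, tiling))
  key <- vapply(universe, function(g)
    paste0(as.integer(g %in% rnaseq), as.integer(g %in% est),
           as.integer(g %in% tiling)), character(1))
  lab <- c("100" = "rnaseq_only", "010" = "est_only", "001" = "tiling_only",
           "110" = "rnaseq_est", "101" = "rnaseq_tiling",
           "011" = "est_tiling", "111" = "all_three")
  counts <- stats::setNames(integer(7), unname(lab))
  tab <- table(key)
  counts[lab[names(tab)]] <- as.integer(tab)
  counts
}

# Linear scan for same-family runs, written independently of the
# implementation's split/cumsum bookkeeping.
oracle_tandem <- function(annotation, family, max_intervening = 1) {
  ord <- annotation[order(annotation$chromosome, annotation$start), ]
  out <- list()
  for (ch in unique(ord$chromosome)) {
    rows <- ord[ord$chromosome == ch, ]
    run <- character(0)
    since_last <- Inf
    for (i in seq_len(nrow(rows))) {
      fams <- trimws(strsplit(ifelse(is.na(rows$family[i]), "",
                                     rows$family[i]), ";")[[1]])
      if (family %in% fams) {
        if (since_last > max_intervening) {
          if (length(run) >= 2) out[[length(out) + 1]] <- run
          run <- character(0)
        }
        run <- c(run, rows$gene_id[i])
        since_last <- 0
      } else {
        since_last <- since_last + 1
      }
    }
    if (length(run) >= 2) out[[length(out) + 1]] <- run
  }
  out
}
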