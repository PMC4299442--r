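#' Two-sided Fisher's exact P for a 2x2 table
#'
#' Exact conditional test on a 2x2 contingency table `[[a, b], [c, d]]`.
#' With all margins fixed the first cell follows a hypergeometric
#' distribution; the two-sided P-value sums the probabilities of all tables
#' whose point probability does not exceed that of the observed table (the
#' "minimum-likelihood" convention, with a small relative tolerance to
#' absorb floating-point ties).
#'
#' @param a,b,c,d Non-negative integer cells of the table, row-wise.
#' @return Two-sided P-value in `[0, 1]`.
#' @seealso [fisher_deg()] for the differential-expression wrapper.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("table cells must be non-negative")
  m <- a + c                     # first-column margin
  n <- b + d
  k <- a + b                     # first-row margin
  if (m + n == 0L) return(1)
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}
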