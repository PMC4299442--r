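#' Per-gene Z-score profiles across stages
#'
#' Standardizes each gene's log2 expression across the selected samples:
#' `Z = (X - mu) / sigma`, where `mu` and `sigma` are the gene's mean and
#' standard deviation over exactly those samples. Large positive Z in one
#' stage marks stage-restricted expression. Genes with `sigma = 0`
#' (constant profiles) are flagged `degenerate` and given Z = 0 everywhere
#' instead of being dropped, so matrices stay aligned.
#'
#' @param log_expr An [expression_matrix()] on the `"log2"` scale.
#' @param samples Samples to standardize over (>= 2); defaults to all.
#' @param population_sd Use the population (n) denominator instead of the
#'   sample (n - 1) default. With only 3-4 stages the choice visibly
#'   rescales Z, so it is exposed rather than hidden.
#' @return Object of class `z_profiles`: list with `z` (gene x sample
#'   matrix), `mu`, `sigma`, `degenerate` (logical) and `samples`.
#' @examples
#' v <- matrix(c(2, 4, 6), 1, dimnames = list("g", c("a", "b", "c")))
#' zscores(expression_matrix(v, "log2"))$z   # -1 0 1
#' @export
zscores <- function(log_expr, samples = NULL, population_sd = FALSE) {
  if (!inherits(log_expr, "expression_matrix"))
    stop("'log_expr' must be an expression_matrix")
  if (log_expr$scale != "log2")
    stop("z-scores are defined on the log2 scale; call log2_transform() first")
  if (is.null(samples)) samples <- colnames(log_expr$values)
  missing <- setdiff(samples, colnames(log_expr$values))
  if (length(missing))
    stop("unknown samples: ", paste(missing, collapse = ", "))
  if (length(samples) < 2)
    stop("z-scores need at least two samples")
  x <- log_expr$values[, samples, drop = FALSE]
  k <- ncol(x)
  mu <- rowMeans(x)
  ss <- rowSums((x - mu)^2)
  sigma <- sqrt(ss / (if (population_sd) k else k - 1))
  degenerate <- sigma == 0
  z <- (x - mu) / ifelse(degenerate, 1, sigma)
  z[degenerate, ] <- 0
  structure(list(z = z, mu = mu, sigma = sigma, degenerate = degenerate,
                 samples = samples), class = "z_profiles")
}

#' @export
print.z_profiles <- function(x, ...) {
  cat("z_profiles: ", nrow(x$z), " genes x ", length(x$samples),
      " samples (", sum(x$degenerate), " degenerate)\n", sep = "")
  invisible(x)
}

#' Histogram of Z-scores in one stage
#'
#' Bins the Z-scores of all non-degenerate genes for one sample into
#' uniform, left-closed bins of width `bin_width` covering the observed
#' range, the form in which stage-specificity distributions are usually
#' plotted (Z on the x-axis, gene numbers on the y-axis). The counts sum
#' to the number of non-degenerate genes.
#'
#' @param profiles A [zscores()] result.
#' @param sample Sample name to summarize.
#' @param bin_width Positive bin width (default 0.25).
#' @return List with `breaks` (bin edges) and `counts` (genes per bin).
#' @export
z_histogram <- function(profiles, sample, bin_width = 0.25) {
  if (!inherits(profiles, "z_profiles"))
    stop("'profiles' must come from zscores()")
  if (!sample %in% profiles$samples)
    stop("unknown sample: ", sample)
  if (bin_width <= 0) stop("'bin_width' must be positive")
  zv <- profiles$z[!profiles$degenerate, sample]
  if (length(zv) == 0)
    return(list(breaks = numeric(0), counts = integer(0)))
  lo <- floor(min(zv) / bin_width) * bin_width
  nbins <- floor((max(zv) - lo) / bin_width) + 1
  idx <- pmin(floor((zv - lo) / bin_width) + 1, nbins)
  list(breaks = lo + bin_width * (0:nbins),
       counts = tabulate(idx, nbins))
}
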