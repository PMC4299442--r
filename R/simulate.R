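#' Configuration for the synthetic floral-transcriptome generator
#'
#' Collects every knob of the synthetic-data generator: genome/annotation
#' structure, the stage-wise expression programs, the negative binomial
#' count model and the platform-evidence model. Defaults describe a
#' three-stage developmental series (inflorescence meristem and two flower
#' stages), single sequencing library per stage of one million mapped reads,
#' a log-normal baseline expression program with median 8 RPKM, and typical
#' bulk RNA-seq overdispersion.
#'
#' @param n_genes Number of genes to simulate.
#' @param stages Ordered character vector of unique stage/sample names.
#' @param library_sizes Named numeric vector of total mapped reads per stage
#'   (recycled from a scalar).
#' @param baseline_log_mean,baseline_log_sd Natural-log mean and sd of the
#'   log-normal baseline true expression (in RPKM units).
#' @param dispersion Negative binomial overdispersion; counts have variance
#'   `mu + dispersion * mu^2`. `0` gives the Poisson limit.
#' @param specific_fraction Fraction of genes planted stage-specific.
#' @param specific_fold Fold by which a planted gene's true mean in its stage
#'   exceeds its mean in every other stage (> 1).
#' @param family_catalog Named integer vector, family name -> member count.
#'   The total must not exceed `n_genes`.
#' @param family_specific_bias Fraction of `specific_family` members forced
#'   to be stage-specific in `specific_family_stage`.
#' @param specific_family,specific_family_stage Family and stage used by
#'   `family_specific_bias` (default: first family, last stage).
#' @param tf_families Families additionally labelled as transcription-factor
#'   families in the annotation.
#' @param gene_type_props Named proportions for gene types
#'   (coding/transposon/pseudogene).
#' @param length_meanlog,length_sdlog,length_min Log-normal cDNA length model
#'   (bp); lengths are truncated below at `length_min`.
#' @param est_detect_slope Logistic slope of EST detection probability per
#'   log2-RPKM unit; `Inf` gives a hard step at `est_midpoint`.
#' @param est_midpoint Log2(1 + RPKM) at which EST detection probability is
#'   0.5.
#' @param probe_coverage Fraction of genes with a tiling-array probe.
#' @param tiling_background Intensity floor (log2 scale) for unexpressed,
#'   probe-covered genes.
#' @param tiling_slope Tiling intensity gain per log2(1 + RPKM) unit.
#' @param array_noise_sd Gaussian noise sd for both array intensities.
#' @param microarray_coverage Fraction of genes with a microarray probe.
#' @param microarray_intercept,microarray_slope Affine map from
#'   log2(1 + RPKM) to microarray intensity.
#' @param seed Integer master seed; the four generator stages consume
#'   documented substreams `seed + 0:3` (annotation, programs, counts,
#'   evidence) so each stage is reproducible in isolation.
#' @return A validated list of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_genes = 200, seed = 7)
#' ann <- simulate_annotation(cfg)
#' head(ann)
#' @export
simulation_config <- function(n_genes = 5000,
                              stages = c("IM", "F1_9", "F12"),
                              library_sizes = 1e6,
                              baseline_log_mean = log(8),
                              baseline_log_sd = 1.2,
                              dispersion = 0.1,
                              specific_fraction = 0.1,
                              specific_fold = 8,
                              family_catalog = c(MADS = 100, MYB = 120,
                                                 bHLH = 110, NAC = 90,
                                                 PPR = 180, Fbox = 200,
                                                 DUF577 = 60, DUF1216 = 45,
                                                 Oleosin = 17, DUF220 = 30),
                              family_specific_bias = 0,
                              specific_family = names(family_catalog)[1],
                              specific_family_stage = stages[length(stages)],
                              tf_families = c("MADS", "MYB", "bHLH", "NAC"),
                              gene_type_props = c(coding = 0.84,
                                                  transposon = 0.13,
                                                  pseudogene = 0.03),
                              length_meanlog = log(1500),
                              length_sdlog = 0.45,
                              length_min = 200,
                              est_detect_slope = 1.5,
                              est_midpoint = 1,
                              probe_coverage = 0.92,
                              tiling_background = 5,
                              tiling_slope = 0.7,
                              array_noise_sd = 0.5,
                              microarray_coverage = 0.7,
                              microarray_intercept = 4,
                              microarray_slope = 0.9,
                              seed = 1L) {
  if (n_genes < 1) stop("'n_genes' must be positive")
  if (length(stages) == 0 || anyDuplicated(stages))
    stop("'stages' must be non-empty and unique")
  if (length(library_sizes) == 1)
    library_sizes <- stats::setNames(rep(library_sizes, length(stages)), stages)
  if (is.null(names(library_sizes)))
    names(library_sizes) <- stages
  if (!setequal(names(library_sizes), stages))
    stop("'library_sizes' names must match 'stages'")
  library_sizes <- library_sizes[stages]
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  fracs <- c(specific_fraction = specific_fraction,
             family_specific_bias = family_specific_bias,
             probe_coverage = probe_coverage,
             microarray_coverage = microarray_coverage)
  bad <- fracs < 0 | fracs > 1
  if (any(bad))
    stop("fractions out of [0, 1]: ", paste(names(fracs)[bad], collapse = ", "))
  if (specific_fold <= 1) stop("'specific_fold' must exceed 1")
  if (dispersion < 0) stop("'dispersion' must be non-negative")
  if (!is.null(family_catalog)) {
    if (is.null(names(family_catalog)) || anyDuplicated(names(family_catalog)))
      stop("'family_catalog' must have unique names")
    if (any(family_catalog < 1)) stop("family sizes must be positive")
    if (sum(family_catalog) > n_genes)
      stop("family_catalog total (", sum(family_catalog),
           ") exceeds n_genes (", n_genes, ")")
  }
  if (abs(sum(gene_type_props) - 1) > 1e-8)
    stop("'gene_type_props' must sum to 1")
  if (family_specific_bias > 0 &&
      (is.null(specific_family) ||
       !specific_family %in% names(family_catalog)))
    stop("'specific_family' must be a family in 'family_catalog'")
  if (family_specific_bias > 0 && !specific_family_stage %in% stages)
    stop("'specific_family_stage' must be one of 'stages'")
  structure(list(
    n_genes = as.integer(n_genes), stages = stages,
    library_sizes = library_sizes,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    dispersion = dispersion,
    specific_fraction = specific_fraction, specific_fold = specific_fold,
    family_catalog = family_catalog,
    family_specific_bias = family_specific_bias,
    specific_family = specific_family,
    specific_family_stage = specific_family_stage,
    tf_families = tf_families,
    gene_type_props = gene_type_props,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    length_min = length_min,
    est_detect_slope = est_detect_slope, est_midpoint = est_midpoint,
    probe_coverage = probe_coverage,
    tiling_background = tiling_background, tiling_slope = tiling_slope,
    array_noise_sd = array_noise_sd,
    microarray_coverage = microarray_coverage,
    microarray_intercept = microarray_intercept,
    microarray_slope = microarray_slope,
    seed = as.integer(seed)), class = "simulation_config")
}

stopifnot_config <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("'config' must come from simulation_config()")
}

#' Simulate a gene annotation table
#'
#' Generates `n_genes` gene models in AGI-style ID order across five
#' chromosomes: log-normal cDNA lengths (median 1500 bp, truncated at
#' 200 bp), 1-based inclusive non-overlapping coordinates increasing with
#' gene ID on each chromosome, gene types drawn from the configured
#' proportions, and family labels matching the family catalog sizes exactly.
#' Families listed in `tf_families` are mirrored into the `tf_family`
#' column.
#'
#' @param config A [simulation_config()].
#' @return A data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `length_bp`, `gene_type`, `family`, `tf_family`.
#' @export
simulate_annotation <- function(config) {
  stopifnot_config(config)
  set.seed(config$seed)          # substream 0: annotation
  n <- config$n_genes
  len <- pmax(config$length_min,
              round(stats::rlnorm(n, config$length_meanlog,
                                  config$length_sdlog)))
  n_chr <- 5L
  chr_of <- ceiling(seq_len(n) / ceiling(n / n_chr))
  idx_in_chr <- stats::ave(seq_len(n), chr_of, FUN = seq_along)
  gene_id <- sprintf("AT%dG%05d", chr_of, idx_in_chr * 10L)
  gap <- sample(200:2000, n, replace = TRUE)
  start <- integer(n)
  end <- integer(n)
  for (ch in unique(chr_of)) {
    i <- which(chr_of == ch)
    s <- cumsum(gap[i] + c(0L, len[i][-length(i)])) + 1L
    start[i] <- s
    end[i] <- s + len[i] - 1L
  }
  gene_type <- sample(names(config$gene_type_props), n, replace = TRUE,
                      prob = config$gene_type_props)
  family <- rep(NA_character_, n)
  if (!is.null(config$family_catalog)) {
    members <- sample(n, sum(config$family_catalog))
    family[members] <- rep(names(config$family_catalog),
                           config$family_catalog)
  }
  tf_family <- ifelse(family %in% config$tf_families, family, NA_character_)
  data.frame(gene_id = gene_id, chromosome = paste0("Chr", chr_of),
             start = start, end = end, length_bp = as.integer(len),
             gene_type = gene_type, family = family, tf_family = tf_family,
             stringsAsFactors = FALSE)
}

#' Simulate stage-wise true expression programs
#'
#' Draws a log-normal baseline true expression (RPKM units) per gene, then
#' plants `specific_fraction` of genes as stage-specific by multiplying
#' their mean in one uniformly chosen stage by `specific_fold`. If
#' `family_specific_bias > 0`, that fraction of the designated family is
#' additionally forced to be specific in `specific_family_stage`,
#' emulating the coherent stage-restricted expression some gene families
#' show in real floral data.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param config The same [simulation_config()].
#' @return A truth table: data.frame with `gene_id`, `family`, `gene_type`,
#'   `length_bp`, `planted_stage` (`NA` for background genes) and one
#'   `mean_<stage>` column of true expression per stage.
#' @export
simulate_programs <- function(annotation, config) {
  stopifnot_config(config)
  set.seed(config$seed + 1L)     # substream 1: programs
  n <- nrow(annotation)
  stages <- config$stages
  baseline <- stats::rlnorm(n, config$baseline_log_mean,
                            config$baseline_log_sd)
  means <- matrix(baseline, n, length(stages),
                  dimnames = list(annotation$gene_id, stages))
  planted <- rep(NA_character_, n)
  n_spec <- round(config$specific_fraction * n)
  if (n_spec > 0) {
    idx <- sample(n, n_spec)
    stage_pick <- sample(stages, n_spec, replace = TRUE)
    planted[idx] <- stage_pick
  }
  if (config$family_specific_bias > 0) {
    fam_idx <- which(annotation$family %in% config$specific_family)
    k <- round(config$family_specific_bias * length(fam_idx))
    if (k > 0) {
      forced <- if (k == length(fam_idx)) fam_idx else sample(fam_idx, k)
      planted[forced] <- config$specific_family_stage
    }
  }
  has <- !is.na(planted)
  means[cbind(which(has), match(planted[has], stages))] <-
    baseline[has] * config$specific_fold
  out <- data.frame(gene_id = annotation$gene_id,
                    family = annotation$family,
                    gene_type = annotation$gene_type,
                    length_bp = annotation$length_bp,
                    planted_stage = planted,
                    stringsAsFactors = FALSE)
  for (s in stages) out[[paste0("mean_", s)]] <- means[, s]
  out
}

truth_means <- function(truth, stages) {
  cols <- paste0("mean_", stages)
  missing <- setdiff(cols, names(truth))
  if (length(missing))
    stop("truth table lacks columns: ", paste(missing, collapse = ", "))
  as.matrix(truth[, cols, drop = FALSE])
}

#' Simulate a read-count matrix from a truth table
#'
#' Counts are negative binomial with mean proportional to true expression
#' times cDNA length times library depth
#' (`mu = mean * length_bp/1000 * N/1e6`, i.e. true means are calibrated in
#' RPKM units) and variance `mu + dispersion * mu^2`. The length bias makes
#' RPKM — not the raw count — the estimator that recovers the planted
#' program. `dispersion = 0` uses the Poisson limit.
#'
#' @param truth Output of [simulate_programs()].
#' @param config The same [simulation_config()].
#' @return A [count_matrix()] with one column per stage and the configured
#'   library sizes.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot_config(config)
  set.seed(config$seed + 2L)     # substream 2: counts
  stages <- config$stages
  means <- truth_means(truth, stages)
  mu <- means * (truth$length_bp / 1000) *
    rep(config$library_sizes / 1e6, each = nrow(means))
  cnt <- if (config$dispersion == 0) {
    matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
           nrow(mu), ncol(mu))
  }
  dimnames(cnt) <- list(truth$gene_id, stages)
  count_matrix(cnt, config$library_sizes)
}

#' Simulate cross-platform detection evidence
#'
#' Produces per-gene EST support, tiling-array probe presence and intensity,
#' and microarray intensity, all driven by the gene's maximal true
#' expression across stages (a transcript expressed anywhere in the series
#' can be tagged or hybridized). EST support is Bernoulli with a logistic
#' probability in log2 expression; array intensities are affine in
#' log2(1 + expression) plus Gaussian noise, with the tiling intensity
#' floored at its background constant. Genes without a probe carry `NA`
#' intensity.
#'
#' @param truth Output of [simulate_programs()].
#' @param config The same [simulation_config()].
#' @return A data.frame with columns `gene_id`, `gene_type`,
#'   `est_supported`, `probe_present`, `tiling_intensity`,
#'   `microarray_intensity`.
#' @export
simulate_platform_evidence <- function(truth, config) {
  stopifnot_config(config)
  set.seed(config$seed + 3L)     # substream 3: evidence
  n <- nrow(truth)
  expr <- apply(truth_means(truth, config$stages), 1, max)
  x <- log2(1 + expr)
  p_est <- if (is.infinite(config$est_detect_slope)) {
    as.numeric(x > config$est_midpoint)
  } else {
    stats::plogis(config$est_detect_slope * (x - config$est_midpoint))
  }
  est_supported <- stats::rbinom(n, 1, p_est) == 1
  probe_present <- stats::rbinom(n, 1, config$probe_coverage) == 1
  tiling <- pmax(config$tiling_background,
                 config$tiling_background + config$tiling_slope * x +
                   stats::rnorm(n, 0, config$array_noise_sd))
  tiling[!probe_present] <- NA_real_
  ma_present <- stats::rbinom(n, 1, config$microarray_coverage) == 1
  microarray <- config$microarray_intercept + config$microarray_slope * x +
    stats::rnorm(n, 0, config$array_noise_sd)
  microarray[!ma_present] <- NA_real_
  data.frame(gene_id = truth$gene_id, gene_type = truth$gene_type,
             est_supported = est_supported, probe_present = probe_present,
             tiling_intensity = tiling, microarray_intensity = microarray,
             stringsAsFactors = FALSE)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper chaining [simulate_annotation()],
#' [simulate_programs()], [simulate_counts()] and
#' [simulate_platform_evidence()], optionally writing the four
#' tab-separated artifacts (`annotation.tsv`, `truth.tsv`, `counts.tsv`,
#' `evidence.tsv`) to a directory.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional directory for the TSV outputs.
#' @return List with `annotation`, `truth`, `counts` (a [count_matrix()])
#'   and `evidence`.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  annotation <- simulate_annotation(config)
  truth <- simulate_programs(annotation, config)
  counts <- simulate_counts(truth, config)
  evidence <- simulate_platform_evidence(truth, config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_annotation(annotation, file.path(outdir, "annotation.tsv"))
    write_tsv(truth, file.path(outdir, "truth.tsv"))
    write_counts(counts, file.path(outdir, "counts.tsv"))
    write_tsv(evidence, file.path(outdir, "evidence.tsv"))
  }
  list(annotation = annotation, truth = truth, counts = counts,
       evidence = evidence)
}
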