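test_that("configuration validation rejects inconsistent settings", {
  expect_error(simulation_config(n_genes = 100,
                                 family_catalog = c(FamA = 101)),
               "exceeds n_genes")
  expect_error(simulation_config(specific_fraction = 1.2), "fractions")
  expect_error(simulation_config(stages = c("A", "A")), "unique")
  expect_error(simulation_config(specific_fold = 1), "specific_fold")
  expect_error(simulation_config(library_sizes = c(IM = 0, F1_9 = 1,
                                                   F12 = 1)),
               "positive")
})

test_that("annotation honours the catalog, ID order and coordinates", {
  cfg <- simulation_config(n_genes = 100, family_catalog = c(FamA = 10),
                           seed = 3)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), 100)
  expect_equal(sum(ann$family == "FamA", na.rm = TRUE), 10)
  expect_false(anyDuplicated(ann$gene_id) > 0)
  expect_true(all(ann$end >= ann$start))
  expect_equal(ann$end - ann$start + 1L, ann$length_bp)
  # non-overlapping and increasing with gene ID on each chromosome
  for (ch in unique(ann$chromosome)) {
    sub <- ann[ann$chromosome == ch, ]
    expect_true(all(diff(sub$start) > 0))
    expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
  }
})

test_that("the generator is deterministic given seed and config", {
  cfg <- simulation_config(n_genes = 300, seed = 11,
                           family_catalog = c(FamA = 20),
                           family_specific_bias = 0.5,
                           specific_family = "FamA")
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$evidence, d2$evidence)
})

test_that("cDNA lengths follow the stated log-normal (median ~1500 bp)", {
  cfg <- simulation_config(n_genes = 2000, seed = 5)
  ann <- simulate_annotation(cfg)
  expect_gt(median(ann$length_bp), 1500 * 0.9)
  expect_lt(median(ann$length_bp), 1500 * 1.1)
  expect_true(all(ann$length_bp >= 200))
})

test_that("expression programs plant the stated fold structure exactly", {
  cfg <- simulation_config(n_genes = 500, seed = 7, specific_fraction = 0.2,
                           specific_fold = 4,
                           family_catalog = c(FamA = 50))
  ann <- simulate_annotation(cfg)
  truth <- simulate_programs(ann, cfg)
  means <- as.matrix(truth[, paste0("mean_", cfg$stages)])
  planted <- !is.na(truth$planted_stage)
  expect_equal(sum(planted), 100)
  for (i in which(planted)) {
    s <- match(truth$planted_stage[i], cfg$stages)
    expect_equal(means[i, s] / means[i, -s],
                 rep(4, length(cfg$stages) - 1),
                 ignore_attr = TRUE)
  }
  # null case: no planting leaves all stage means identical
  cfg0 <- simulation_config(n_genes = 200, seed = 7, specific_fraction = 0,
                            family_catalog = c(FamA = 20))
  t0 <- simulate_programs(simulate_annotation(cfg0), cfg0)
  m0 <- as.matrix(t0[, paste0("mean_", cfg0$stages)])
  expect_equal(apply(m0, 1, max), apply(m0, 1, min))
})

test_that("family bias forces the designated family into one stage", {
  cfg <- simulation_config(n_genes = 400, seed = 13,
                           family_catalog = c(FamA = 30, FamB = 30),
                           family_specific_bias = 1,
                           specific_family = "FamA",
                           specific_family_stage = "F12",
                           specific_fraction = 0)
  ann <- simulate_annotation(cfg)
  truth <- simulate_programs(ann, cfg)
  fam_a <- truth$family == "FamA" & !is.na(truth$family)
  expect_true(all(truth$planted_stage[fam_a] == "F12"))
  expect_true(all(is.na(truth$planted_stage[!fam_a])))
})

test_that("counts follow the length-biased negative binomial model", {
  stages <- c("A", "B")
  # Poisson limit: mean 100 over 10000 replicate genes recovered within 2%
  # (10 RPKM x 1 kb x 10M reads -> mu = 100)
  cfg <- simulation_config(n_genes = 10000, stages = stages,
                           library_sizes = 1e7, dispersion = 0, seed = 19)
  tr <- manual_truth(10000, stages, mean_value = 10)
  cm <- simulate_counts(tr, cfg)
  expect_gt(mean(cm$counts[, "A"]), 98)
  expect_lt(mean(cm$counts[, "A"]), 102)
  expect_true(all(cm$counts >= 0))
  expect_true(all(cm$counts == floor(cm$counts)))
  # zero true mean gives zero counts always
  tr0 <- manual_truth(500, stages, mean_value = 0)
  cm0 <- simulate_counts(tr0, cfg)
  expect_true(all(cm0$counts == 0))
})

test_that("doubling the library size doubles the expected count", {
  stages <- c("A", "B")
  tr <- manual_truth(5000, stages, mean_value = 50)
  cfg1 <- simulation_config(n_genes = 5000, stages = stages,
                            library_sizes = 1e6, seed = 23)
  cfg2 <- simulation_config(n_genes = 5000, stages = stages,
                            library_sizes = 2e6, seed = 23)
  m1 <- mean(simulate_counts(tr, cfg1)$counts)
  m2 <- mean(simulate_counts(tr, cfg2)$counts)
  expect_gt(m2 / m1, 2 * 0.97)
  expect_lt(m2 / m1, 2 * 1.03)
})

test_that("platform evidence tracks expression as configured", {
  cfg <- simulation_config(n_genes = 1000, seed = 29,
                           est_detect_slope = Inf, est_midpoint = 2)
  ann <- simulate_annotation(cfg)
  truth <- simulate_programs(ann, cfg)
  ev <- simulate_platform_evidence(truth, cfg)
  # infinite slope: EST support is a hard indicator above the midpoint
  expr <- apply(as.matrix(truth[, paste0("mean_", cfg$stages)]), 1, max)
  expect_identical(ev$est_supported, log2(1 + expr) > 2)
  # probe coverage ~ binomial expectation
  cfg2 <- simulation_config(n_genes = 1000, seed = 31,
                            probe_coverage = 0.9)
  ev2 <- simulate_platform_evidence(simulate_programs(
    simulate_annotation(cfg2), cfg2), cfg2)
  expect_gt(sum(ev2$probe_present), 900 - 40)   # ~4 binomial sd
  expect_lt(sum(ev2$probe_present), 900 + 40)
  # intensity floored at background; NA exactly when no probe
  expect_true(all(ev2$tiling_intensity >= cfg2$tiling_background,
                  na.rm = TRUE))
  expect_identical(is.na(ev2$tiling_intensity), !ev2$probe_present)
  # a (near-)zero-expression gene sits at the floor up to one-sided noise
  tr0 <- manual_truth(2000, cfg2$stages, mean_value = 0)
  ev0 <- simulate_platform_evidence(tr0, cfg2)
  expect_true(all(ev0$tiling_intensity >= cfg2$tiling_background,
                  na.rm = TRUE))
  expect_lt(mean(ev0$tiling_intensity, na.rm = TRUE),
            cfg2$tiling_background + cfg2$array_noise_sd)
})
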