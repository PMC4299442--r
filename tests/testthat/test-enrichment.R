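test_that("family detection tables reproduce printed-style fractions", {
  ann <- family_annotation(list(NBARC = 167, LSM = 26, Eighth = 8),
                           extra = 20)
  in_set <- c(sprintf("NBARC_%03d", 1:108), sprintf("LSM_%03d", 1:26),
              sprintf("Eighth_%03d", 1))
  tab <- family_detection_table(in_set, ann)
  row <- function(f) tab[tab$family == f, ]
  expect_equal(row("NBARC")$percent, 0.65)    # 108/167
  expect_equal(row("NBARC")$total, 167)
  expect_equal(row("LSM")$percent, 1.00)      # 26/26, fully detected
  expect_equal(row("Eighth")$percent, 0.13)   # 1/8 = 0.125, halves round up
  # family absent from the set
  tab0 <- family_detection_table(character(0), ann)
  expect_true(all(tab0$percent == 0))
  # filters and ordering
  tabf <- family_detection_table(in_set, ann, min_total = 20)
  expect_setequal(tabf$family, c("NBARC", "LSM"))
  expect_equal(tabf$family[1], "LSM")         # sorted by percent desc
})

test_that("multi-domain genes count once per family they carry", {
  ann <- tiny_annotation(c("g1", "g2", "g3"))
  ann$family <- c("FamA;FamB", "FamA", NA)
  tab <- family_detection_table(c("g1"), ann)
  expect_equal(tab$total[tab$family == "FamA"], 2)
  expect_equal(tab$in_set[tab$family == "FamA"], 1)
  expect_equal(tab$in_set[tab$family == "FamB"], 1)
})

test_that("family enrichment matches the hypergeometric oracle", {
  # exactly proportional family -> odds ratio 1 -> P = 1
  ann <- family_annotation(list(FamA = 10), extra = 30)
  set_prop <- c(sprintf("FamA_%03d", 1:5), sprintf("BG_%04d", 1:15))
  enr <- family_enrichment(set_prop, ann)
  expect_equal(enr$p_value[enr$family == "FamA"], 1)
  # 20-gene universe, 10-gene set, family of 5 entirely in the set
  ann2 <- family_annotation(list(FamB = 5), extra = 15)
  set2 <- c(sprintf("FamB_%03d", 1:5), sprintf("BG_%04d", 1:5))
  enr2 <- family_enrichment(set2, ann2)
  expect_equal(enr2$p_value[enr2$family == "FamB"],
               oracle_fisher_p(5, 5, 0, 10), tolerance = 1e-12)
  # random configurations vs the oracle
  set.seed(13)
  for (i in 1:25) {
    total <- sample(3:40, 1)
    ann3 <- family_annotation(list(F1 = total), extra = 60)
    set3 <- sample(ann3$gene_id, sample(5:50, 1))
    enr3 <- family_enrichment(set3, ann3)
    a <- sum(sprintf("F1_%03d", 1:total) %in% set3)
    expect_equal(enr3$p_value[enr3$family == "F1"],
                 oracle_fisher_p(a, length(set3) - a, total - a,
                                 nrow(ann3) - length(set3) - total + a),
                 tolerance = 1e-12)
  }
  expect_error(family_enrichment(c("not_in_universe"), ann),
               "outside the universe")
})

test_that("a planted stage-specific family ranks first in enrichment", {
  hits <- 0
  for (i in 1:5) {
    cfg <- simulation_config(n_genes = 2000, seed = 600 + i,
                             family_specific_bias = 1,
                             specific_family = "DUF1216",
                             specific_family_stage = "F12")
    d <- simulate_dataset(cfg)
    set <- stage_specific(d$counts, d$annotation, "F12", fold = 4)
    enr <- family_enrichment(set, d$annotation)
    hits <- hits + (nrow(enr) > 0 && enr$family[1] == "DUF1216")
  }
  expect_equal(hits, 5)
})

test_that("set overlap significance uses the membership table", {
  big <- sprintf("u%05d", 1:1000)
  r <- set_overlap_test(big[1:10], big[501:510], 1000)
  expect_equal(r$overlap, 0)
  expect_lte(r$p_value, 1)
  # degenerate: both sets are the whole universe
  r2 <- set_overlap_test(big, big, 1000)
  expect_equal(r2$overlap, 1000)
  expect_equal(r2$p_value, 1)
  expect_error(set_overlap_test(big[1:600], big[401:1000], 900), "smaller")
  # DEG-vs-ChIP-target margins: 13628 x 4505 in a 27416-gene universe,
  # overlap 2506 - P must equal the exhaustive enumeration at the margins
  u <- seq_len(27416)
  set_a <- as.character(u[1:13628])
  set_b <- as.character(c(u[1:2506], u[13629:(13628 + 1999)]))
  r3 <- set_overlap_test(set_a, set_b, 27416)
  expect_equal(r3$overlap, 2506)
  expect_equal(r3$p_value,
               oracle_fisher_p(2506, 13628 - 2506, 4505 - 2506,
                               27416 - 13628 - 4505 + 2506),
               tolerance = 1e-9)
})

test_that("tandem arrays are maximal same-family runs", {
  ann <- tiny_annotation(sprintf("g%02d", 1:8))
  ann$family <- c("X", "X", "X", NA, NA, "X", "X", NA)
  arr <- detect_tandem_arrays(ann, "X", max_intervening = 1)
  expect_equal(nrow(arr), 2)
  expect_equal(arr$members[1], "g01,g02,g03")
  expect_equal(arr$n_members, c(3L, 2L))
  expect_equal(arr$span_start[1], ann$start[1])
  expect_equal(arr$span_end[1], ann$end[3])
  # members at ranks 1 and 4 with one intervening gene allowed: no array
  ann2 <- tiny_annotation(sprintf("g%02d", 1:4))
  ann2$family <- c("X", NA, NA, "X")
  expect_equal(nrow(detect_tandem_arrays(ann2, "X", 1)), 0)
  expect_equal(nrow(detect_tandem_arrays(ann2, "X", 2)), 1)
  # a bp cap can split an adjacency-valid run
  ann3 <- tiny_annotation(c("a", "b"))
  ann3$start <- c(1000L, 900000L); ann3$end <- c(1999L, 900999L)
  ann3$family <- c("X", "X")
  expect_equal(nrow(detect_tandem_arrays(ann3, "X")), 1)
  expect_equal(nrow(detect_tandem_arrays(ann3, "X",
                                         max_distance_bp = 10000)), 0)
})

test_that("tandem detection matches a linear-scan oracle on random data", {
  set.seed(14)
  for (i in 1:20) {
    n <- 40
    ann <- tiny_annotation(sprintf("g%02d", 1:n))
    ann$chromosome <- sample(c("Chr1", "Chr2"), n, replace = TRUE)
    ann$family <- sample(c("X", "Y", NA), n, replace = TRUE,
                         prob = c(0.3, 0.2, 0.5))
    gap <- sample(0:2, 1)
    arr <- detect_tandem_arrays(ann, "X", gap)
    want <- oracle_tandem(ann, "X", gap)
    expect_equal(nrow(arr), length(want))
    if (length(want))
      expect_equal(arr$members,
                   vapply(want, paste, character(1), collapse = ","))
    # arrays are disjoint
    all_members <- unlist(strsplit(arr$members, ","))
    expect_false(anyDuplicated(all_members) > 0)
  }
})
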