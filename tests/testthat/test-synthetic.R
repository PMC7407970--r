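test_that("config validation catches bad inputs", {
  expect_error(cohort_config(seed = 1, n_tumor = 0), "positive")
  expect_error(cohort_config(seed = 1, stage_probs = c(0.5, 0.5, 0, 0.1)),
               "stage_probs")
  expect_error(cohort_config(seed = 1, dispersion = -1), "positive")
  expect_error(cohort_config(n_tumor = 10), "seed")
  expect_error(
    cohort_config(seed = 1, planted_mmr_ids = "mir-999", n_mirna = 5),
    "undeclared")
  expect_error(
    cohort_config(seed = 1, n_mirna = 5, planted_mmr_ids = "mir-001",
                  planted_edges = data.frame(mirna = "mir-001",
                                             gene = "g9999", sign = -1,
                                             effect = 1)),
    "undeclared genes")
})

test_that("identical configs give bit-identical cohorts", {
  cfg <- benchmark_cohort_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(benchmark_cohort_config(seed = 11))
  expect_identical(a, b)
  c <- generate_cohort(benchmark_cohort_config(seed = 12))
  expect_false(identical(a$mirna_counts, c$mirna_counts))
})

test_that("cohort structure: dimensions, metadata and ground truth", {
  cfg <- benchmark_cohort_config(seed = 13)
  ch <- generate_cohort(cfg)
  expect_equal(dim(ch$mirna_counts), c(10, 400))
  expect_equal(dim(ch$mrna_counts), c(200, 400))
  expect_equal(ch$metadata$sample_id, colnames(ch$mirna_counts))
  expect_equal(sum(ch$metadata$condition == "tumor"), 300)
  expect_true(all(ch$metadata$stage[ch$metadata$condition == "tumor"] %in%
                    c("I", "II", "III", "IV")))
  expect_true(all(is.na(ch$metadata$time[ch$metadata$condition ==
                                           "normal"])))
  expect_true(all(ch$metadata$time[ch$metadata$condition == "tumor"] >= 0))
  expect_true(all(ch$mirna_counts >= 0))
  expect_equal(ch$mirna_counts, round(ch$mirna_counts))
  # every planted edge's gene has a role entry
  expect_true(all(ch$truth$planted_edges$gene %in%
                    names(ch$truth$driver_roles)))
  expect_equal(unname(ch$truth$driver_roles["g0001"]), "tsg")
  expect_equal(unname(ch$truth$driver_roles["g0061"]), "oncogene")
  expect_equal(unname(ch$truth$driver_roles["g0150"]), "none")
})

test_that("unplanted feature means match the configured baseline", {
  cfg <- cohort_config(n_tumor = 150, n_normal = 100, n_mirna = 6,
                       n_mrna = 60, mirna_base_mean = 500,
                       mrna_base_mean = 300, libsize_lognormal_sd = 0,
                       seed = 14)
  ch <- generate_cohort(cfg)
  n <- 250
  # MC standard error of a feature's mean under NB(mu, disp):
  # sqrt((mu + disp*mu^2)/n)
  se_mir <- sqrt((500 + 0.1 * 500^2) / n)
  se_rna <- sqrt((300 + 0.1 * 300^2) / n)
  expect_true(all(abs(rowMeans(ch$mirna_counts) - 500) < 3 * se_mir))
  expect_true(all(abs(rowMeans(ch$mrna_counts) - 300) < 3 * se_rna))
})

test_that("a fully null cohort produces ~5% raw DE rejections", {
  cfg <- cohort_config(n_tumor = 200, n_normal = 200, n_mirna = 5,
                       n_mrna = 1000, libsize_lognormal_sd = 0.2,
                       seed = 15)
  ch <- generate_cohort(cfg)
  cond <- factor(ch$metadata$condition, levels = c("normal", "tumor"))
  de <- nb_differential_expression(ch$mrna_counts, cond)
  rate <- mean(de$pvalue <= 0.05, na.rm = TRUE)
  # binomial error band around the nominal rate, 1000 features
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
  # and essentially nothing survives BH
  expect_lte(sum(de$padj <= 0.05, na.rm = TRUE), 3)
})

test_that("mock databases honour recall, precision and the identity case", {
  truth <- list(
    planted_edges = data.frame(
      mirna = rep(sprintf("mir-%03d", 1:20), each = 50),
      gene = sprintf("g%04d", 1:1000), sign = -1, effect = 1),
    mirna_ids = sprintf("mir-%03d", 1:20),
    gene_ids = sprintf("g%04d", 1:1000))

  ident <- generate_target_databases(truth, n_dbs = 1, recall = 1,
                                     precision = 1, seed = 1)
  expect_equal(ident$databases$db1,
               truth$planted_edges[, c("mirna", "gene")])

  half <- generate_target_databases(truth, n_dbs = 1, recall = 0.5,
                                    precision = 1, seed = 2)
  k <- nrow(half$databases$db1)
  expect_gte(k, qbinom(0.005, 1000, 0.5))
  expect_lte(k, qbinom(0.995, 1000, 0.5))

  # stated precision holds in expectation
  prec <- generate_target_databases(truth, n_dbs = 1, recall = 0.8,
                                    precision = 0.25, seed = 3)
  db <- prec$databases$db1
  true_key <- paste(truth$planted_edges$mirna, truth$planted_edges$gene)
  frac_true <- mean(paste(db$mirna, db$gene) %in% true_key)
  expect_lt(abs(frac_true - 0.25), 0.05)

  # union recall dominates any single database's recall
  multi <- generate_target_databases(truth, n_dbs = 3, recall = 0.6,
                                     precision = 0.5, seed = 4)
  uni_key <- paste(multi$union$mirna, multi$union$gene)
  single_recall <- vapply(multi$databases, function(d) {
    mean(true_key %in% paste(d$mirna, d$gene))
  }, numeric(1))
  expect_gte(mean(true_key %in% uni_key), max(single_recall))

  empty <- list(planted_edges = truth$planted_edges[0, ],
                mirna_ids = truth$mirna_ids, gene_ids = truth$gene_ids)
  expect_error(generate_target_databases(empty, precision = 0.5),
               "empty true edge set")
})

test_that("driver annotation fractions and degenerate cases", {
  genes <- sprintf("g%03d", 1:100)
  all_onc <- generate_driver_annotation(genes, 1, 0, 0, seed = 1)
  expect_true(all(all_onc$role == "oncogene"))

  mix <- generate_driver_annotation(genes, 0.1, 0.1, 0.05, seed = 2)
  expect_equal(as.vector(table(mix$role)[c("oncogene", "tsg", "dual")]),
               c(10L, 10L, 5L))
  expect_equal(sum(mix$role == "none"), 75)

  none <- generate_driver_annotation(genes, 0, 0, 0, seed = 3)
  expect_true(all(none$role == "none"))
  # downstream: OA undefined for every regulator under an all-none map
  tl <- tally_driver_targets(
    data.frame(gene = genes[1:5]),
    stats::setNames(none$role, none$gene),
    data.frame(feature = genes, log2FoldChange = 1))
  expect_false(oncogenic_activity(tl)$defined)

  expect_error(generate_driver_annotation(genes, 0.6, 0.5, 0), "sum")
})

test_that("cohorts round-trip through the TSV writers", {
  cfg <- cohort_config(n_tumor = 12, n_normal = 8, n_mirna = 4,
                       n_mrna = 10, seed = 16)
  ch <- generate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(ch, dir)
  expect_true(all(file.exists(file.path(
    dir, c("counts_mirna.tsv", "counts_mrna.tsv", "metadata.tsv",
           "truth_edges.tsv", "truth_driver_roles.tsv", "truth.json")))))
  m <- read_counts_tsv(file.path(dir, "counts_mirna.tsv"))
  expect_equal(m, ch$mirna_counts)
  md <- read_tsv_table(file.path(dir, "metadata.tsv"))
  expect_equal(md$sample_id, ch$metadata$sample_id)
  unlink(dir, recursive = TRUE)
})
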