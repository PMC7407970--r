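rk <- function(x) rank(x, ties.method = "average") / length(x)

test_that("MI is symmetric, monotone-invariant and zero for constants", {
  set.seed(31)
  x <- rnorm(100); y <- rnorm(100)
  expect_identical(mutual_information(x, y), mutual_information(y, x))
  # rank-based estimator: exact invariance under monotone transforms
  expect_identical(mutual_information(x, y),
                   mutual_information(exp(x), y^3 + 2 * y))
  expect_equal(mutual_information(rep(1, 50), rnorm(50)), 0)
  expect_error(mutual_information(1:10, 1:9), "equal length")
  expect_error(mutual_information(1:5, 5:1), "at least 8")
  expect_gte(mutual_information(x, y), 0)
})

test_that("MI matches the Gaussian closed form at rho = 0.8", {
  target <- -0.5 * log(1 - 0.8^2)      # 0.5108 nats
  mis <- vapply(1:3, function(s) {
    set.seed(s)
    x <- rnorm(2000)
    y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(2000)
    mutual_information(x, y)
  }, numeric(1))
  expect_true(all(abs(mis - target) <= 0.08))
})

test_that("independent data stays below the p=0.01 threshold almost always", {
  thr <- mi_threshold(1000, p_value = 0.01, n_null = 500, seed = 5)
  set.seed(32)
  below <- vapply(1:40, function(i) {
    x <- rnorm(1000)
    mutual_information(x, sample(x)) < thr
  }, logical(1))
  expect_gte(mean(below), 0.95)
})

test_that("MI threshold is seeded, shrinks with n, and matches its oracle", {
  t1 <- mi_threshold(100, 0.01, n_null = 200, seed = 9)
  t2 <- mi_threshold(100, 0.01, n_null = 200, seed = 9)
  expect_identical(t1, t2)

  expect_lt(mi_threshold(500, 0.01, n_null = 300, seed = 10),
            mi_threshold(50, 0.01, n_null = 300, seed = 10))

  # independent permutation oracle at the same n and p
  set.seed(33)
  null <- vapply(1:600, function(i) {
    mutual_information(rnorm(80), rnorm(80))
  }, numeric(1))
  oracle_q <- unname(stats::quantile(null, 0.99))
  got <- mi_threshold(80, 0.01, n_null = 600, seed = 11)
  expect_lt(abs(got - oracle_q), 0.02)

  expect_error(mi_threshold(100, 0), "p_value")
  expect_error(mi_threshold(100, 0.01, n_null = 10), "n_null")
})

test_that("DPI removes the weakest edge of a triangle and respects tolerance", {
  tri <- data.frame(a = c("x", "x", "y"), b = c("y", "z", "z"),
                    mi = c(0.5, 0.4, 0.1))
  pruned <- dpi_prune(tri)
  expect_equal(nrow(pruned), 2)
  expect_false(any(pruned$mi == 0.1))
  expect_equal(nrow(dpi_prune(tri, tolerance = 1)), 3)
  expect_error(dpi_prune(tri, tolerance = -1), "non-negative")
})

test_that("DPI equals the exhaustive oracle on random small graphs", {
  set.seed(34)
  for (i in 1:200) {
    g <- random_graph(sample(3:6, 1))
    if (nrow(g) == 0) next
    tol <- sample(c(0, 0, 0.1, 0.5), 1)
    expect_identical(canon_edges(dpi_prune(g, tol)),
                     canon_edges(dpi_oracle(g, tol)))
  }
})

test_that("bootstrap consensus: single replicate identity and containment", {
  set.seed(35)
  n <- 60
  x <- matrix(rnorm(3 * n), 3, dimnames = list(c("m1", "m2", "m3"), NULL))
  y <- matrix(rnorm(5 * n), 5,
              dimnames = list(paste0("g", 1:5), NULL))
  y[1, ] <- x[1, ] + 0.3 * rnorm(n)
  thr <- mi_threshold(n, 0.01, n_null = 200, seed = 2)
  one <- bootstrap_consensus(x, y, n_boot = 1, threshold = thr, seed = 3)
  expect_true(all(one$support == 1))

  multi <- bootstrap_consensus(x, y, n_boot = 8, threshold = thr, seed = 3)
  expect_true(all(multi$support <= 8))
  expect_true(all(multi$mi >= 0))
  expect_error(bootstrap_consensus(x[, 1:4], y[, 1:4], 2, thr), "at least 8")
})

test_that("bootstrap consensus recovers planted edges with few false ones", {
  stats <- vapply(1:3, function(s) {
    cfg <- cohort_config(n_tumor = 300, n_normal = 10, n_mirna = 1,
                         n_mrna = 25, planted_mmr_ids = "mir-001",
                         planted_edges = data.frame(
                           mirna = "mir-001", gene = sprintf("g%04d", 1:5),
                           sign = -1, effect = 1.5),
                         stage_trend = 1.0, seed = 600 + s)
    ch <- generate_cohort(cfg)
    tum <- ch$metadata$sample_id[ch$metadata$condition == "tumor"]
    sf <- depth_factors(rbind(ch$mirna_counts, ch$mrna_counts))
    mv <- vst_transform(ch$mirna_counts, sf)
    gv <- vst_transform(ch$mrna_counts, sf)
    thr <- mi_threshold(length(tum), 1e-4, n_null = 500, seed = 700 + s)
    net <- bootstrap_consensus(mv[, tum, drop = FALSE], gv[, tum],
                               n_boot = 20, threshold = thr,
                               seed = 800 + s)
    key <- paste(net$mirna, net$gene)
    truth <- paste("mir-001", sprintf("g%04d", 1:5))
    c(sum(truth %in% key), sum(!(key %in% truth)))
  }, numeric(2))
  expect_true(all(stats[1, ] == 5))   # all 5 planted edges, every seed
  expect_true(all(stats[2, ] <= 2))   # at most 2 false edges
})

test_that("raising the MI threshold never adds consensus edges", {
  set.seed(36)
  n <- 80
  x <- matrix(rnorm(2 * n), 2, dimnames = list(c("m1", "m2"), NULL))
  y <- matrix(rnorm(6 * n), 6, dimnames = list(paste0("g", 1:6), NULL))
  y[1, ] <- x[1, ] + 0.5 * rnorm(n)
  y[2, ] <- x[2, ] + 0.5 * rnorm(n)
  lo <- bootstrap_consensus(x, y, n_boot = 6, threshold = 0.02, seed = 4)
  hi <- bootstrap_consensus(x, y, n_boot = 6, threshold = 0.10, seed = 4)
  expect_true(all(paste(hi$mirna, hi$gene) %in% paste(lo$mirna, lo$gene)))
})

test_that("node degrees count links and sum to the edge count", {
  net <- data.frame(mirna = c("m1", "m1", "m1"),
                    gene = c("g1", "g2", "g3"))
  deg <- node_degree(net)
  expect_equal(deg$mirna$degree, 3)
  expect_equal(deg$gene$degree, rep(1, 3))

  empty <- node_degree(data.frame(mirna = character(0),
                                  gene = character(0)))
  expect_equal(nrow(empty$mirna), 0)

  set.seed(37)
  rand <- unique(data.frame(
    mirna = sample(paste0("m", 1:6), 40, replace = TRUE),
    gene = sample(paste0("g", 1:10), 40, replace = TRUE)))
  deg2 <- node_degree(rand)
  expect_equal(sum(deg2$mirna$degree), nrow(rand))
  expect_equal(sum(deg2$gene$degree), nrow(rand))
})
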