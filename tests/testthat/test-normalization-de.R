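test_that("size factors: identity, scaling and a hand-computed toy", {
  m <- matrix(c(5, 10, 3, 5, 10, 3), ncol = 2)
  expect_equal(unname(size_factors(m)), c(1, 1))

  a <- c(4, 9, 25, 12)
  m2 <- cbind(A = a, B = 2 * a)
  sf <- size_factors(m2)
  expect_equal(unname(sf["B"] / sf["A"]), 2)

  # 3x3 toy, factors worked out by hand from the median-of-ratios
  # definition: rows (2,4,8), (3,3,3), (10,5,20) -> factors (1, 1, 2)
  toy <- rbind(c(2, 4, 8), c(3, 3, 3), c(10, 5, 20))
  expect_equal(unname(size_factors(toy)), c(1, 1, 2))
})

test_that("size factors are scale-equivariant and error without a reference row", {
  set.seed(41)
  m <- null_counts(30, 6, mean = 100)
  sf <- size_factors(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 5
  # factors are defined up to a common rescaling (the geometric-mean
  # reference moves too), so the equivariance shows up in the ratios
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2 / sf2[1]),
               unname(sf / sf[1]) * c(1, 1, 5, 1, 1, 1),
               tolerance = 1e-12)

  bad <- rbind(c(0, 5, 5), c(5, 0, 5), c(5, 5, 0))
  expect_error(size_factors(bad), "pseudocount")
  expect_silent(size_factors(bad, pseudocount = 1))
})

test_that("depth factors ignore a large planted shift", {
  set.seed(42)
  n <- 120
  libf <- stats::rlnorm(n, 0, 0.3)
  grp <- rep(c(1, 0), each = n / 2)   # 'tumors' first
  null_mu <- outer(rep(200, 50), libf)
  shift_mu <- outer(rep(200, 50), libf) *
    2^(-1.5 * matrix(grp, 50, n, byrow = TRUE))
  counts <- rbind(
    matrix(rnbinom(length(null_mu), mu = null_mu, size = 10), nrow = 50),
    matrix(rnbinom(length(shift_mu), mu = shift_mu, size = 10), nrow = 50))
  df <- depth_factors(counts)
  # anchored estimate tracks the true library factors without a group bias
  ratio <- log2(df / libf)
  expect_lt(abs(mean(ratio[grp == 1]) - mean(ratio[grp == 0])), 0.1)
  # plain median-of-ratios is visibly biased on the same data
  sf <- size_factors(counts, pseudocount = 1)
  ratio2 <- log2(sf / libf)
  expect_gt(abs(mean(ratio2[grp == 1]) - mean(ratio2[grp == 0])), 0.3)
})

test_that("vst transform is zero-preserving, monotone and flattens variance", {
  expect_equal(vst_transform(matrix(0), factors = 1)[1, 1], 0)

  set.seed(7)
  m <- null_counts(20, 10, mean = 50)
  v1 <- vst_transform(m, factors = rep(1, 10))
  m2 <- m
  m2[3, 4] <- m2[3, 4] * 2
  v2 <- vst_transform(m2, factors = rep(1, 10))
  expect_gte(v2[3, 4], v1[3, 4])
  expect_true(all(v2 >= v1 - 1e-12))

  # variance flattening across a 100-fold mean range
  set.seed(8)
  means <- rep(c(10, 100, 1000, 10000), each = 50)
  counts <- matrix(rnbinom(200 * 200, mu = means, size = 1 / 0.3),
                   nrow = 200)
  raw_var <- tapply(apply(counts, 1, var), means, mean)
  tr_var <- tapply(apply(vst_transform(counts, rep(1, 200)), 1, var),
                   means, mean)
  expect_gt(max(raw_var) / min(raw_var), 50)
  expect_lt(max(tr_var) / min(tr_var), 5)
})

test_that("BH adjustment matches the brute-force definition", {
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:60) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # NA passthrough
  p <- c(0.01, NA, 0.04, 0.2)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[-2], bh_oracle(p[-2]))
})

test_that("BH discoveries are nested across levels and never below p", {
  set.seed(10)
  p <- stats::runif(300)^2
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-12))
  d05 <- which(adj <= 0.05)
  d10 <- which(adj <= 0.10)
  expect_true(all(d05 %in% d10))
})

test_that("NB DE handles constant features and flips under label swap", {
  set.seed(11)
  m <- null_counts(50, 20, mean = 100)
  m[1, ] <- 77                       # constant, non-zero
  m[2, ] <- 0                        # all zero
  grp <- factor(rep(c("normal", "tumor"), each = 10),
                levels = c("normal", "tumor"))
  de <- nb_differential_expression(m, grp, factors = rep(1, 20))
  expect_equal(de$log2FoldChange[1], 0)
  expect_equal(de$pvalue[1], 1)
  expect_true(is.na(de$pvalue[2]) && is.na(de$padj[2]))

  de_sw <- nb_differential_expression(m, grp, ref = "tumor",
                                      factors = rep(1, 20))
  expect_equal(de_sw$log2FoldChange[-2], -de$log2FoldChange[-2])
  expect_equal(de_sw$pvalue, de$pvalue)

  expect_error(
    nb_differential_expression(m, factor(c("a", rep("b", 19)))),
    "at least 2")
})

test_that("NB DE recovers a planted 4-fold change", {
  lfcs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    m <- null_counts(10, 200, mean = 100, dispersion = 0.1)
    grp <- factor(rep(c("normal", "tumor"), each = 100),
                  levels = c("normal", "tumor"))
    m[1, 101:200] <- stats::rnbinom(100, mu = 400, size = 10)
    nb_differential_expression(m, grp,
                               factors = rep(1, 200))$log2FoldChange[1]
  }, numeric(1))
  expect_lt(abs(stats::median(lfcs) - 2), 0.3)
})

test_that("NB DE type-I error is near nominal under the null", {
  set.seed(12)
  m <- null_counts(2000, 200, mean = 150, dispersion = 0.1)
  grp <- factor(rep(c("normal", "tumor"), each = 100),
                levels = c("normal", "tumor"))
  de <- nb_differential_expression(m, grp, factors = rep(1, 200))
  rate <- mean(de$pvalue <= 0.05, na.rm = TRUE)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
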