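#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over features
#' whose geometric mean across samples is positive, of the ratio between
#' the sample's count and the feature's geometric mean. This is the
#' standard count-normalization estimator for RNA-seq; factors are
#' reported unscaled, so only their ratios are meaningful.
#'
#' @param counts non-negative count matrix, features in rows.
#' @param pseudocount value added to every count before estimation
#'   (default 0). Use a positive pseudocount when no feature is observed
#'   in all samples.
#' @return positive numeric vector, one factor per sample (named when
#'   `counts` has colnames).
#' @export
size_factors <- function(counts, pseudocount = 0) {
  counts <- as.matrix(counts) + pseudocount
  if (any(counts < 0)) stop("counts must be non-negative")
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) {
    stop("no feature has positive counts in all samples; ",
         "rerun with a positive 'pseudocount'")
  }
  log_ratio <- log(counts[use, , drop = FALSE]) - log_gm[use]
  sf <- exp(apply(log_ratio, 2, stats::median))
  stats::setNames(sf, colnames(counts))
}

#' Stability-anchored sequencing-depth factors
#'
#' Median-of-ratios size factors computed only over the `anchor_frac`
#' fraction of features with the smallest cross-sample variance of
#' `log2(count + 1)`. The plain estimator assumes most features are not
#' differentially expressed; at fixture scale a cohort can carry strong
#' one-directional expression shifts in a large fraction of its (few)
#' features, which biases the per-group medians. Features whose
#' abundance is stable across the whole cohort are unaffected by such
#' shifts, so anchoring the ratio median on them recovers the
#' library-depth signal (the same idea as least-variable-gene
#' normalization).
#'
#' @param counts count matrix, features in rows (typically the combined
#'   miRNA + mRNA matrix).
#' @param anchor_frac fraction of least-variable features used as
#'   normalization anchors (default 0.5).
#' @param pseudocount passed to [size_factors()] (default 1, for
#'   robustness to zeros in the anchor set).
#' @return positive numeric vector of per-sample factors.
#' @export
depth_factors <- function(counts, anchor_frac = 0.5, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (anchor_frac <= 0 || anchor_frac > 1) {
    stop("anchor_frac must lie in (0, 1]")
  }
  lv <- apply(log2(counts + 1), 1, stats::var)
  anchor <- lv <= stats::quantile(lv, anchor_frac)
  size_factors(counts[anchor, , drop = FALSE], pseudocount = pseudocount)
}

#' Variance-stabilizing transform (normalized log2)
#'
#' A deterministic stand-in for a fitted variance-stabilizing transform:
#' `log2(count / size_factor + 1)`. Monotone per sample and finite for
#' all non-negative counts.
#'
#' @param counts count matrix, features in rows.
#' @param factors per-sample positive size factors; estimated with
#'   [size_factors()] when omitted.
#' @return numeric matrix of the same shape as `counts`.
#' @export
vst_transform <- function(counts, factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- size_factors(counts)
  if (length(factors) != ncol(counts)) {
    stop("one size factor per sample required")
  }
  if (any(factors <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2, factors, "/") + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with the cumulative-minimum monotonicity step.
#' `NA` values are passed through and do not count toward the number of
#' tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  o <- order(p[ok], decreasing = TRUE)
  ro <- ok[o]
  adj <- cummin(p[ro] * m / (m:1))
  out[ro] <- pmin(adj, 1)
  out
}

#' Negative-binomial differential expression (Wald test)
#'
#' A per-feature NB model on size-factor-normalized counts: group means
#' are compared on the log2 scale with a Wald test whose standard error
#' comes from the NB mean-variance relation, using a single
#' method-of-moments dispersion pooled across the two groups. This is a
#' deliberately simple test - no shrinkage, no outlier handling - whose
#' output contract (baseMean, log2FoldChange, pvalue, padj) matches what
#' downstream stages consume.
#'
#' Features with zero counts everywhere get `NA` statistics and are
#' excluded from the BH adjustment. A half-count pseudo-mean guards the
#' fold change when one group mean is exactly zero.
#'
#' @param counts count matrix, features in rows, samples in columns.
#' @param condition vector/factor of two group labels, one per sample.
#' @param ref reference (denominator) level; defaults to the first factor
#'   level. Positive log2FoldChange means the non-reference group is
#'   higher.
#' @param factors optional precomputed size factors.
#' @return data frame with columns `feature`, `baseMean`,
#'   `log2FoldChange`, `pvalue`, `padj`.
#' @export
nb_differential_expression <- function(counts, condition, ref = NULL,
                                       factors = NULL) {
  counts <- as.matrix(counts)
  condition <- factor(condition)
  if (nlevels(condition) != 2) stop("exactly two groups required")
  if (!is.null(ref)) condition <- stats::relevel(condition, ref = ref)
  if (any(table(condition) < 2)) {
    stop("each group needs at least 2 samples (dispersion unidentifiable)")
  }
  if (is.null(factors)) factors <- size_factors(counts, pseudocount = 1)
  q <- sweep(counts, 2, factors, "/")           # normalized counts
  ia <- condition == levels(condition)[1]       # reference group
  ib <- !ia
  na <- sum(ia); nb <- sum(ib)
  inv_a <- mean(1 / factors[ia]); inv_b <- mean(1 / factors[ib])

  m_a <- rowMeans(q[, ia, drop = FALSE])
  m_b <- rowMeans(q[, ib, drop = FALSE])
  v_a <- apply(q[, ia, drop = FALSE], 1, stats::var)
  v_b <- apply(q[, ib, drop = FALSE], 1, stats::var)

  # method-of-moments dispersion, pooled across groups, floored
  disp_of <- function(v, m, inv) ifelse(m > 0, (v - m * inv) / m^2, NA_real_)
  d_a <- disp_of(v_a, m_a, inv_a)
  d_b <- disp_of(v_b, m_b, inv_b)
  w <- cbind(d_a * (na - 1), d_b * (nb - 1))
  denom <- (na - 1) * (!is.na(d_a)) + (nb - 1) * (!is.na(d_b))
  disp <- rowSums(w, na.rm = TRUE) / pmax(denom, 1)
  disp <- pmax(disp, 1e-8)

  delta <- 0.5 * mean(1 / factors)              # half a normalized count
  mu_a <- m_a + delta * (m_a == 0 | m_b == 0)
  mu_b <- m_b + delta * (m_a == 0 | m_b == 0)
  lfc <- log2(mu_b / mu_a)

  var_ma <- (m_a * inv_a + disp * m_a^2) / na
  var_mb <- (m_b * inv_b + disp * m_b^2) / nb
  se_ln <- sqrt(var_ma / pmax(mu_a, delta)^2 + var_mb / pmax(mu_b, delta)^2)
  z <- ifelse(se_ln > 0, (log(mu_b) - log(mu_a)) / se_ln, 0)
  pvalue <- 2 * stats::pnorm(-abs(z))

  all_zero <- rowSums(counts) == 0
  lfc[all_zero] <- NA_real_
  pvalue[all_zero] <- NA_real_

  data.frame(
    feature = rownames(counts),
    baseMean = rowMeans(q),
    log2FoldChange = lfc,
    pvalue = pvalue,
    padj = bh_adjust(pvalue),
    stringsAsFactors = FALSE
  )
}
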