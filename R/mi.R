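rank_coord <- function(x) rank(x, ties.method = "average") / length(x)

#' Mutual information between two expression profiles
#'
#' Rank-based adaptive-partitioning estimator (the ARACNe family's
#' choice), in nats. Both vectors are mapped to average ranks, so the
#' estimate is invariant under strictly monotone transforms of either
#' argument. A constant vector yields MI 0 by convention.
#'
#' @param x,y numeric vectors of equal length (>= 8).
#' @return non-negative mutual information in nats.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 8) stop("need at least 8 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  mi_ap_pair_cpp(rank_coord(x), rank_coord(y))
}

#' Permutation-null MI significance threshold
#'
#' The (1 - p_value) quantile of the MI between independently permuted
#' vectors of length `n_samples`, estimated from `n_null` seeded
#' permutations. When the requested tail is deeper than the permutation
#' sample can resolve (`n_null * p_value < 10`) the upper tail is
#' extrapolated with an exponential peaks-over-threshold fit, as in the
#' ARACNe family, instead of returning the unstable sample maximum.
#'
#' With `resample = TRUE` every null draw additionally resamples the
#' sample indices with replacement before ranking, reproducing the
#' duplicate-sample structure of a bootstrap replicate; use this for
#' thresholds fed to [bootstrap_consensus()], whose rank-based MI is
#' inflated by duplicated samples even under independence.
#'
#' @param n_samples sample count of the data the threshold will be
#'   applied to.
#' @param p_value nominal tail probability in (0, 1).
#' @param n_null number of null permutations (>= 100).
#' @param seed integer RNG seed.
#' @param resample draw the null under bootstrap resampling
#'   (default `FALSE`: plain permutation null).
#' @return numeric MI threshold (nats).
#' @export
mi_threshold <- function(n_samples, p_value = 1e-4, n_null = 1000,
                         seed = 1, resample = FALSE) {
  if (p_value <= 0 || p_value >= 1) stop("p_value must lie in (0, 1)")
  if (n_null < 100) stop("n_null must be at least 100")
  if (n_samples < 8) stop("need at least 8 samples")
  set.seed(seed)
  base <- seq_len(n_samples) / n_samples
  null <- vapply(seq_len(n_null), function(i) {
    y <- sample(base)
    if (resample) {
      idx <- sample.int(n_samples, n_samples, replace = TRUE)
      mi_ap_pair_cpp(rank_coord(base[idx]), rank_coord(y[idx]))
    } else {
      mi_ap_pair_cpp(base, y)
    }
  }, numeric(1))
  if (n_null * p_value >= 10) {
    return(unname(stats::quantile(null, 1 - p_value, type = 7)))
  }
  # exponential excess fit over the top 5% (>= 20 draws)
  k <- max(20L, as.integer(0.05 * n_null))
  t0 <- unname(stats::quantile(null, 1 - k / n_null, type = 7))
  excess <- null[null > t0] - t0
  if (length(excess) == 0) return(t0)
  beta <- mean(excess)
  t0 + beta * log(length(excess) / (n_null * p_value))
}

# Rank-coordinate matrix: samples in rows, features in columns.
rank_coord_matrix <- function(m) apply(m, 2, rank_coord)

# All cross MI between rows of two feature x sample matrices.
mi_cross <- function(xmat, ymat) {
  out <- mi_ap_cross_cpp(rank_coord_matrix(t(xmat)),
                         rank_coord_matrix(t(ymat)))
  dimnames(out) <- list(rownames(xmat), rownames(ymat))
  out
}
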