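# Independent oracles used across the suite. Each is a deliberately
# naive implementation (loops, exhaustive enumeration) kept separate
# from the package's code paths.

# Benjamini-Hochberg by definition: sort, scale by m/rank, then take the
# running minimum from the right with an explicit loop.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  adj <- numeric(m)
  for (k in seq_len(m)) adj[k] <- min(q[k:m], 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# DPI by exhaustive triple enumeration over all node triples.
dpi_oracle <- function(edges, tolerance = 0) {
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  w <- as.numeric(edges[[3]])
  key <- paste(pmin(a, b), pmax(a, b))
  stopifnot(!anyDuplicated(key))
  nodes <- sort(unique(c(a, b)))
  wmap <- stats::setNames(w, key)
  drop <- character(0)
  if (length(nodes) >= 3) {
    for (tri in utils::combn(nodes, 3, simplify = FALSE)) {
      ks <- c(paste(tri[1], tri[2]), paste(tri[1], tri[3]),
              paste(tri[2], tri[3]))
      if (!all(ks %in% names(wmap))) next
      ws <- wmap[ks]
      mn_idx <- which(ws == min(ws))
      if (length(mn_idx) != 1) next
      if (all(ws[mn_idx] < (1 - tolerance) * ws[-mn_idx])) {
        drop <- c(drop, ks[mn_idx])
      }
    }
  }
  edges[!(key %in% drop), , drop = FALSE]
}

# Two-group log-rank by the textbook observed-minus-expected sums.
logrank_oracle <- function(time, event, group) {
  group <- as.integer(factor(group))
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# A random undirected weighted graph on n nodes (each possible edge kept
# with probability p_edge).
random_graph <- function(n_nodes, p_edge = 0.6) {
  prs <- t(utils::combn(seq_len(n_nodes), 2))
  keep <- stats::runif(nrow(prs)) < p_edge
  prs <- prs[keep, , drop = FALSE]
  data.frame(a = sprintf("n%d", prs[, 1]), b = sprintf("n%d", prs[, 2]),
             mi = stats::runif(nrow(prs)), stringsAsFactors = FALSE)
}

# Null NB count matrix (no planted structure).
null_counts <- function(n_feat, n_samp, mean = 200, dispersion = 0.1,
                        libsd = 0) {
  libf <- if (libsd > 0) stats::rlnorm(n_samp, 0, libsd) else rep(1, n_samp)
  mu <- outer(rep(mean, n_feat), libf)
  m <- matrix(stats::rnbinom(n_feat * n_samp, mu = mu,
                             size = 1 / dispersion), nrow = n_feat)
  rownames(m) <- sprintf("f%04d", seq_len(n_feat))
  colnames(m) <- sprintf("s%04d", seq_len(n_samp))
  m
}

# All permutations of 1:n as rows (n! x n matrix), recursion.
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
  }))
}

canon_edges <- function(df) {
  key <- paste(pmin(df[[1]], df[[2]]), pmax(df[[1]], df[[2]]))
  sort(key)
}
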