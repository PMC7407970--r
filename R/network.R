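#' Data processing inequality pruning
#'
#' For every closed triangle in an undirected weighted edge list, the
#' strictly weakest edge is marked when its MI is below
#' `(1 - tolerance)` times both other edges; all marked edges are then
#' removed at once. Marking happens against the original weights, so the
#' result does not depend on any edge ordering (documented convention).
#' Ties for the minimum mark nothing.
#'
#' @param edges data frame whose first three columns are node, node, MI
#'   weight.
#' @param tolerance non-negative DPI tolerance; 0 is strict, 1 disables
#'   pruning.
#' @return the pruned edge data frame (same columns, original row
#'   order).
#' @export
dpi_prune <- function(edges, tolerance = 0) {
  if (tolerance < 0) stop("tolerance must be non-negative")
  if (nrow(edges) == 0) return(edges)
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  w <- as.numeric(edges[[3]])
  if (any(a == b)) stop("self loops are not allowed")
  # canonical undirected key
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edges in input")
  wmap <- stats::setNames(w, key)
  nodes <- sort(unique(c(a, b)))
  adj <- lapply(stats::setNames(nodes, nodes), function(n) character(0))
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], b[i])
    adj[[b[i]]] <- c(adj[[b[i]]], a[i])
  }
  drop <- character(0)
  for (i in seq_along(a)) {
    u <- lo[i]; v <- hi[i]
    common <- intersect(adj[[u]], adj[[v]])
    for (wn in common[common > v]) {     # each triangle visited once
      k_uv <- key[i]
      k_uw <- paste(u, wn, sep = "\r")
      k_vw <- paste(v, wn, sep = "\r")
      ws <- c(wmap[k_uv], wmap[k_uw], wmap[k_vw])
      mn <- min(ws)
      is_min <- ws == mn
      if (sum(is_min) == 1) {
        others <- ws[!is_min]
        if (all(mn < (1 - tolerance) * others)) {
          drop <- c(drop, c(k_uv, k_uw, k_vw)[is_min])
        }
      }
    }
  }
  edges[!(key %in% drop), , drop = FALSE]
}

spearman_sign <- function(x, y) {
  r <- stats::cor(rank(x, ties.method = "average"),
                  rank(y, ties.method = "average"))
  if (is.na(r)) 0L else as.integer(sign(r))
}

#' Bootstrap-consensus miRNA-mRNA network
#'
#' ARACNe-style inference: in each bootstrap replicate, samples are
#' resampled with replacement, all miRNA x gene mutual informations are
#' computed, edges below `threshold` are discarded and the data
#' processing inequality is applied. Triangles are closed in the
#' ARACNe-AP regulator-hub convention: two miRNAs sharing a target gene,
#' with the miRNA-miRNA MI (computed on the same replicate) as the third
#' edge. The consensus keeps edges whose support count is inconsistent
#' with a Poisson null of spurious rediscovery at a
#' Bonferroni-corrected `consensus_alpha`. The Poisson mean is
#' estimated from the fraction of candidate miRNA x gene pairs never
#' observed across replicates (`mu0 = -log(n_zero / n_pairs)`): unlike
#' the average support, this zero-count moment estimator stays valid
#' whether truly-regulated pairs are a small or a large fraction of the
#' candidates. A spurious-rediscovery null is needed because bootstrap
#' resampling duplicates samples, which inflates the rank-based MI of
#' even independent pairs past a clean-data threshold in a minority of
#' replicates. Consensus edges then receive a final DPI pass with MI
#' evaluated on the original (non-resampled) samples: per-replicate DPI
#' decisions are noisy, and this deterministic pass removes indirect
#' stage- or co-regulation-mediated edges that slipped through in
#' enough replicates to gain support. With `n_boot = 1` the single
#' replicate's network is returned as-is.
#'
#' Edge directionality - which MI cannot provide - is the sign of the
#' Spearman correlation between miRNA and gene on the original
#' (non-resampled) samples.
#'
#' @param mirna_expr,mrna_expr expression matrices (features x samples,
#'   VST scale) sharing sample columns.
#' @param n_boot number of bootstrap replicates (default 100).
#' @param threshold MI significance threshold, e.g. from
#'   [mi_threshold()].
#' @param tolerance DPI tolerance (default 0).
#' @param consensus_alpha family-wise alpha for the consensus test.
#' @param seed integer RNG seed.
#' @return data frame with columns `mirna`, `gene`, `mi` (mean over
#'   supporting replicates), `support`, `direction_sign`.
#' @export
bootstrap_consensus <- function(mirna_expr, mrna_expr, n_boot = 100,
                                threshold, tolerance = 0,
                                consensus_alpha = 0.05, seed = 1) {
  mirna_expr <- as.matrix(mirna_expr)
  mrna_expr <- as.matrix(mrna_expr)
  n <- ncol(mirna_expr)
  if (ncol(mrna_expr) != n) stop("matrices must share sample columns")
  if (!is.null(colnames(mirna_expr)) && !is.null(colnames(mrna_expr)) &&
      !identical(colnames(mirna_expr), colnames(mrna_expr))) {
    stop("matrices must share sample columns")
  }
  if (n < 8) stop("need at least 8 samples")
  if (n_boot < 1) stop("n_boot must be at least 1")
  mir_ids <- rownames(mirna_expr)
  gene_ids <- rownames(mrna_expr)
  p <- length(mir_ids); q <- length(gene_ids)

  set.seed(seed)
  support <- matrix(0L, p, q, dimnames = list(mir_ids, gene_ids))
  mi_sum <- matrix(0, p, q, dimnames = list(mir_ids, gene_ids))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    xm <- mirna_expr[, idx, drop = FALSE]
    ym <- mrna_expr[, idx, drop = FALSE]
    mi <- mi_cross(xm, ym)
    pass <- which(mi > threshold, arr.ind = TRUE)
    if (nrow(pass) == 0) next
    keep <- prune_bipartite(pass, mi, xm, tolerance)
    ij <- keep[, 1] + (keep[, 2] - 1) * p
    support[ij] <- support[ij] + 1L
    mi_sum[ij] <- mi_sum[ij] + mi[ij]
  }

  found <- which(support > 0, arr.ind = TRUE)
  if (nrow(found) == 0) {
    return(data.frame(mirna = character(0), gene = character(0),
                      mi = numeric(0), support = integer(0),
                      direction_sign = integer(0)))
  }
  cnt <- support[found]
  if (n_boot > 1) {
    n_zero <- sum(support == 0)
    mu0 <- -log(max(n_zero, 0.5) / (p * q))
    pval <- stats::ppois(cnt - 1, mu0, lower.tail = FALSE)
    sig <- pval <= consensus_alpha / (p * q)
    found <- found[sig, , drop = FALSE]
    cnt <- cnt[sig]
  }
  if (nrow(found) == 0) {
    return(data.frame(mirna = character(0), gene = character(0),
                      mi = numeric(0), support = integer(0),
                      direction_sign = integer(0)))
  }
  if (n_boot > 1 && nrow(found) > 1) {
    mi_full <- mi_cross(mirna_expr, mrna_expr)
    keep <- prune_bipartite(found, mi_full, mirna_expr, tolerance)
    kept_key <- keep[, 1] + (keep[, 2] - 1) * p
    sel <- (found[, 1] + (found[, 2] - 1) * p) %in% kept_key
    found <- found[sel, , drop = FALSE]
    cnt <- cnt[sel]
  }
  ij <- found[, 1] + (found[, 2] - 1) * p
  dir <- vapply(seq_len(nrow(found)), function(k) {
    spearman_sign(mirna_expr[found[k, 1], ], mrna_expr[found[k, 2], ])
  }, integer(1))
  out <- data.frame(
    mirna = mir_ids[found[, 1]],
    gene = gene_ids[found[, 2]],
    mi = mi_sum[ij] / cnt,
    support = cnt,
    direction_sign = dir,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# DPI within one bootstrap replicate: `pass` is a two-column index matrix
# (miRNA row, gene col) of thresholded edges, `mi` the full MI matrix,
# `xm` the resampled miRNA expression used for closing miRNA-miRNA MI.
prune_bipartite <- function(pass, mi, xm, tolerance) {
  p <- nrow(mi)
  if (p < 2 || nrow(pass) < 2) return(pass)
  edges <- data.frame(
    a = paste0("m\r", pass[, 1]),
    b = paste0("g\r", pass[, 2]),
    mi = mi[pass],
    stringsAsFactors = FALSE
  )
  # miRNA pairs sharing at least one passing target close triangles
  by_gene <- split(pass[, 1], pass[, 2])
  prs <- unique(do.call(rbind, lapply(by_gene, function(ms) {
    ms <- sort(unique(ms))
    if (length(ms) < 2) return(NULL)
    t(utils::combn(ms, 2))
  })))
  if (!is.null(prs) && nrow(prs) > 0) {
    xr <- rank_coord_matrix(t(xm))
    mm <- mi_ap_pairs_cpp(xr, prs[, 1], prs[, 2])
    edges <- rbind(edges, data.frame(
      a = paste0("m\r", prs[, 1]),
      b = paste0("m\r", prs[, 2]),
      mi = mm,
      stringsAsFactors = FALSE
    ))
  }
  kept <- dpi_prune(edges, tolerance)
  kept <- kept[startsWith(kept$a, "m\r") & startsWith(kept$b, "g\r"), ]
  cbind(
    as.integer(sub("^m\r", "", kept$a)),
    as.integer(sub("^g\r", "", kept$b))
  )
}

#' Node degrees of a bipartite regulatory network
#'
#' miRNA degree is its number of target genes; gene degree is its number
#' of regulating miRNAs. Both degree sums equal the edge count.
#'
#' @param network edge data frame with columns `mirna` and `gene`.
#' @return list of two data frames, `mirna` and `gene`, each with
#'   columns `node` and `degree`, sorted by decreasing degree.
#' @export
node_degree <- function(network) {
  deg_tab <- function(v) {
    if (length(v) == 0) {
      return(data.frame(node = character(0), degree = integer(0)))
    }
    t <- table(v)
    out <- data.frame(node = names(t), degree = as.integer(t),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$degree, out$node), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(mirna = deg_tab(network$mirna), gene = deg_tab(network$gene))
}
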