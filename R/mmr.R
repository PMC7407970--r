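#' Signed z-score gene signature from a DE table
#'
#' Each gene's differential-expression p-value is converted to a normal
#' quantile and signed by its fold-change direction:
#' `z = sign(log2FoldChange) * qnorm(p / 2, lower.tail = FALSE)`, capped
#' at +/- 10 (which also absorbs p = 0). Features with missing
#' statistics are dropped.
#'
#' @param de DE table with columns `feature`, `log2FoldChange`,
#'   `pvalue`.
#' @return named numeric vector of signed z-scores.
#' @export
gene_signature <- function(de) {
  keep <- !is.na(de$pvalue) & !is.na(de$log2FoldChange)
  de <- de[keep, , drop = FALSE]
  z <- stats::qnorm(pmax(de$pvalue, 1e-300) / 2, lower.tail = FALSE)
  z <- sign(de$log2FoldChange) * pmin(z, 10)
  stats::setNames(z, de$feature)
}

#' Build regulons from a consensus network
#'
#' One regulon per miRNA with at least `min_size` targets. The mode of
#' each target is the network's `direction_sign` (edges with sign 0 are
#' dropped); the weight is bootstrap support normalized by the largest
#' support in the network, so weights lie in (0, 1].
#'
#' @param network consensus edge table from [bootstrap_consensus()].
#' @param min_size minimum regulon size (default 10 at genome scale; use
#'   3 for small fixtures).
#' @return named list of regulons, each a data frame with columns
#'   `gene`, `mode`, `weight`.
#' @export
build_regulons <- function(network, min_size = 10) {
  if (nrow(network) == 0) return(list())
  network <- network[network$direction_sign != 0, , drop = FALSE]
  if (nrow(network) == 0) return(list())
  wmax <- max(network$support)
  regs <- split(network, network$mirna)
  regs <- lapply(regs, function(e) {
    data.frame(gene = e$gene, mode = as.integer(e$direction_sign),
               weight = e$support / wmax, stringsAsFactors = FALSE)
  })
  regs[vapply(regs, nrow, integer(1)) >= min_size]
}

#' Regulon enrichment against a gene signature
#'
#' Single-tail weighted-mean enrichment: the raw score is
#' `sum(weight * z(target)) / sqrt(sum(weight^2))` over regulon targets
#' present in the signature. Its sign therefore follows the expression
#' direction of the targets - a negative score means the regulon's
#' targets sit in the downregulated side of the tumor-vs-normal
#' signature. Significance comes from a size-matched gene-sampling null:
#' `n_null` random gene sets of the same size drawn from the signature
#' (weights kept), giving `nes = (raw - mean(null)) / sd(null)` and a
#' two-sided empirical p with add-one smoothing.
#'
#' @param regulon data frame with columns `gene`, `mode`, `weight`.
#' @param signature named z-score vector from [gene_signature()].
#' @param n_null number of null gene sets (default 1000).
#' @param seed optional integer seed for the null draws.
#' @return list with `nes`, `p`, `raw`, `size` (targets used).
#' @export
enrichment_nes <- function(regulon, signature, n_null = 1000, seed = NULL) {
  hit <- regulon$gene %in% names(signature)
  if (!any(hit)) stop("no regulon target present in the signature")
  regulon <- regulon[hit, , drop = FALSE]
  w <- regulon$weight
  norm <- sqrt(sum(w^2))
  raw <- sum(w * signature[regulon$gene]) / norm
  k <- nrow(regulon)
  if (!is.null(seed)) set.seed(seed)
  genes <- names(signature)
  null <- vapply(seq_len(n_null), function(i) {
    sum(w * signature[sample(genes, k)]) / norm
  }, numeric(1))
  mu <- mean(null)
  sdv <- stats::sd(null)
  nes <- (raw - mu) / sdv
  p <- (1 + sum(abs(null - mu) >= abs(raw - mu))) / (n_null + 1)
  list(nes = nes, p = p, raw = raw, size = k)
}

#' Call master regulators at an FDR cutoff
#'
#' BH-adjusts the enrichment p-values over all tested regulons and
#' returns those at or below the cutoff, NES sign retained.
#'
#' @param calls data frame with columns `mirna`, `nes`, `pvalue`,
#'   `regulon_size`.
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @return the input table with an `fdr` column, subset to calls with
#'   `fdr <= fdr_cutoff`.
#' @export
call_master_regulators <- function(calls, fdr_cutoff = 0.05) {
  if (nrow(calls) == 0) {
    calls$fdr <- numeric(0)
    return(calls)
  }
  calls$fdr <- bh_adjust(calls$pvalue)
  out <- calls[!is.na(calls$fdr) & calls$fdr <= fdr_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Master-regulator analysis of a consensus network
#'
#' Convenience wrapper: builds regulons, scores each against the
#' signature with a seeded null, BH-adjusts and returns the full table
#' plus the significant calls.
#'
#' @param network consensus edge table.
#' @param de_mrna tumor-vs-normal mRNA DE table (signature source).
#' @param min_size minimum regulon size.
#' @param n_null null gene sets per regulon.
#' @param seed integer seed (one stream for all regulons, applied in
#'   sorted miRNA order for determinism).
#' @param fdr_cutoff FDR threshold for calls.
#' @return list with `table` (all tested regulons: `mirna`, `nes`,
#'   `pvalue`, `fdr`, `regulon_size`) and `mmr` (significant subset).
#' @export
mmr_analysis <- function(network, de_mrna, min_size = 10, n_null = 1000,
                         seed = 1, fdr_cutoff = 0.05) {
  signature <- gene_signature(de_mrna)
  regulons <- build_regulons(network, min_size = min_size)
  if (length(regulons) == 0) {
    empty <- data.frame(mirna = character(0), nes = numeric(0),
                        pvalue = numeric(0), fdr = numeric(0),
                        regulon_size = integer(0))
    return(list(table = empty, mmr = empty, regulons = regulons))
  }
  regulons <- regulons[order(names(regulons))]
  set.seed(seed)
  rows <- lapply(names(regulons), function(id) {
    res <- enrichment_nes(regulons[[id]], signature, n_null = n_null)
    data.frame(mirna = id, nes = res$nes, pvalue = res$p,
               regulon_size = res$size, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_adjust(tab$pvalue)
  tab <- tab[, c("mirna", "nes", "pvalue", "fdr", "regulon_size")]
  list(table = tab, mmr = call_master_regulators(
         tab[, c("mirna", "nes", "pvalue", "regulon_size")],
         fdr_cutoff = fdr_cutoff),
       regulons = regulons)
}
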