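#' Convert clinical stage labels to ordinal codes
#'
#' AJCC stage labels I-IV are mapped to 1-4. Sub-stages collapse to their
#' parent stage ("IIa", "IIB" -> 2). Unknown labels become `NA`.
#'
#' @param stage character vector of stage labels.
#' @return integer vector of stage codes 1-4 (NA when unknown).
#' @export
stage_to_numeric <- function(stage) {
  s <- toupper(gsub("[ABCabc]+$", "", trimws(as.character(stage))))
  code <- c(I = 1L, II = 2L, III = 3L, IV = 4L)
  out <- unname(code[s])
  out
}

#' Spearman correlation between expression and clinical stage
#'
#' Average-rank tie handling; the p-value uses the t approximation on the
#' correlation with n - 2 degrees of freedom. Samples with missing stage
#' are dropped; normals must be excluded by the caller.
#'
#' @param expr numeric expression values (one per tumor sample).
#' @param stage ordinal stage codes 1-4 (see [stage_to_numeric()]).
#' @return list with `rho`, `p` and `n` (samples used). `rho` is `NA`
#'   when either vector is constant.
#' @export
spearman_stage_correlation <- function(expr, stage) {
  if (length(expr) != length(stage)) stop("expr and stage lengths differ")
  keep <- !is.na(expr) & !is.na(stage)
  expr <- expr[keep]; stage <- as.numeric(stage[keep])
  n <- length(expr)
  if (n < 3) stop("need at least 3 samples with non-missing stage")
  rx <- rank(expr, ties.method = "average")
  ry <- rank(stage, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' miRNAs consistently upregulated across all clinical stages
#'
#' A miRNA is retained when in every one of the four per-stage contrasts
#' it passes `fdr <= fdr_cutoff` and `log2FoldChange >= lfc_cutoff`, and
#' its expression correlates positively with stage
#' (`rho > 0`, `p <= corr_p`). miRNAs missing from any stage table fail.
#'
#' @param de_tables named list of exactly four per-stage DE tables
#'   (columns `feature`, `log2FoldChange`, `padj`), stage-k tumors vs
#'   normals.
#' @param correlations data frame with columns `feature`, `rho`, `p`
#'   (from [spearman_stage_correlation()] per miRNA).
#' @param fdr_cutoff per-stage FDR threshold (default 0.05).
#' @param lfc_cutoff per-stage minimum log2 fold change (default +0.5).
#' @param corr_p stage-correlation p-value threshold (default 0.05).
#' @return list with `consistent` (sorted miRNA ids) and `audit` (full
#'   per-miRNA table with per-stage statistics and the `consistent`
#'   flag).
#' @export
filter_consistent_upregulated <- function(de_tables, correlations,
                                          fdr_cutoff = 0.05,
                                          lfc_cutoff = 0.5,
                                          corr_p = 0.05) {
  if (length(de_tables) != 4) stop("exactly four stage DE tables required")
  if (is.null(names(de_tables))) names(de_tables) <- paste0("stage", 1:4)
  features <- sort(unique(unlist(lapply(de_tables, `[[`, "feature"))))
  audit <- data.frame(feature = features, stringsAsFactors = FALSE)
  pass_all <- rep(TRUE, length(features))
  for (k in seq_along(de_tables)) {
    tab <- de_tables[[k]]
    idx <- match(features, tab$feature)
    lfc <- tab$log2FoldChange[idx]
    fdr <- tab$padj[idx]
    ok <- !is.na(lfc) & !is.na(fdr) & fdr <= fdr_cutoff & lfc >= lfc_cutoff
    ok[is.na(idx)] <- FALSE
    audit[[paste0(names(de_tables)[k], "_lfc")]] <- lfc
    audit[[paste0(names(de_tables)[k], "_fdr")]] <- fdr
    pass_all <- pass_all & ok
  }
  ci <- match(features, correlations$feature)
  rho <- correlations$rho[ci]
  rp <- correlations$p[ci]
  corr_ok <- !is.na(rho) & !is.na(rp) & rho > 0 & rp <= corr_p
  audit$spearman_rho <- rho
  audit$spearman_p <- rp
  audit$consistent <- pass_all & corr_ok
  list(consistent = sort(audit$feature[audit$consistent]), audit = audit)
}
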