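#' Normalize miRNA/gene identifiers to a shared namespace
#'
#' Lowercases and strips the species prefix `hsa-`, so that database and
#' network identifiers written in different conventions match.
#'
#' @param ids character vector of identifiers.
#' @return normalized identifiers.
#' @export
normalize_feature_ids <- function(ids) {
  sub("^hsa-", "", tolower(trimws(ids)))
}

#' Filter a network by target-database evidence
#'
#' Keeps an edge iff its (miRNA, gene) pair appears in the union of the
#' supplied databases (the union, not the intersection, because it has
#' the higher sensitivity). Identifiers are normalized on both sides
#' before matching; a per-edge `evidence` column records which
#' databases support it.
#'
#' @param network edge table with columns `mirna` and `gene`.
#' @param dbs named list of edge sets, each a data frame with columns
#'   `mirna` and `gene`.
#' @param allow_empty set `TRUE` to explicitly skip filtering when no
#'   database is supplied (default errors, since an empty union would
#'   silently drop everything).
#' @return the filtered network with an `evidence` column
#'   (comma-separated database names).
#' @export
filter_by_databases <- function(network, dbs, allow_empty = FALSE) {
  if (length(dbs) == 0) {
    if (allow_empty) {
      network$evidence <- "unfiltered"
      return(network)
    }
    stop("no databases supplied; pass allow_empty = TRUE to skip the filter")
  }
  if (is.null(names(dbs)) || any(names(dbs) == "")) {
    names(dbs) <- paste0("db", seq_along(dbs))
  }
  net_key <- paste(normalize_feature_ids(network$mirna),
                   normalize_feature_ids(network$gene), sep = "\r")
  evid <- vector("list", nrow(network))
  for (nm in names(dbs)) {
    db <- dbs[[nm]]
    db_key <- unique(paste(normalize_feature_ids(db$mirna),
                           normalize_feature_ids(db$gene), sep = "\r"))
    hit <- net_key %in% db_key
    evid[hit] <- lapply(evid[hit], c, nm)
  }
  keep <- lengths(evid) > 0
  out <- network[keep, , drop = FALSE]
  out$evidence <- vapply(evid[keep], paste, character(1), collapse = ",")
  rownames(out) <- NULL
  out
}
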