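#' Classify a target's regulation direction from its fold change
#'
#' Direction of each target in the tumor-vs-normal contrast: `"up"` for
#' a positive log2 fold change, `"down"` for a negative one. Exactly
#' zero or missing fold changes are excluded from the driver tallies
#' (`NA` returned).
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @return character vector: `"up"`, `"down"` or `NA`.
#' @export
classify_target_direction <- function(log2fc) {
  out <- rep(NA_character_, length(log2fc))
  out[!is.na(log2fc) & log2fc > 0] <- "up"
  out[!is.na(log2fc) & log2fc < 0] <- "down"
  out
}

#' Construct a driver-target tally
#'
#' Counts of driver targets of one regulator, split by role and
#' regulation direction: upregulated oncogenes (UONC), downregulated
#' tumor suppressors (DTSG), downregulated oncogenes (DONC),
#' upregulated tumor suppressors (UTSG) and dual-role genes (ONCTSG,
#' counted once regardless of direction). `T` is their sum.
#'
#' @param UONC,DTSG,DONC,UTSG,ONCTSG non-negative integer counts.
#' @return list of class `driver_tally`.
#' @export
driver_tally <- function(UONC = 0, DTSG = 0, DONC = 0, UTSG = 0,
                         ONCTSG = 0) {
  vals <- c(UONC = UONC, DTSG = DTSG, DONC = DONC, UTSG = UTSG,
            ONCTSG = ONCTSG)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("tallies must be non-negative integers")
  }
  out <- as.list(vals)
  out$T <- sum(vals)
  structure(out, class = "driver_tally")
}

#' Tally the driver targets of a regulon
#'
#' Each regulon target is looked up in the driver annotation and the DE
#' table. Genes with role `none` (or absent from the annotation) are
#' ignored; dual-role genes increment only `ONCTSG` (and the total);
#' oncogenes and tumor suppressors are split by the sign of their
#' tumor-vs-normal log2 fold change. Targets with zero or missing fold
#' change are excluded.
#'
#' @param regulon data frame with a `gene` column.
#' @param annotation named character vector (or data frame with columns
#'   `gene`, `role`) mapping genes to roles in
#'   `c("oncogene", "tsg", "dual", "none")`.
#' @param de DE table with columns `feature`, `log2FoldChange`.
#' @return a [driver_tally()].
#' @export
tally_driver_targets <- function(regulon, annotation, de) {
  if (is.data.frame(annotation)) {
    annotation <- stats::setNames(as.character(annotation$role),
                                  annotation$gene)
  }
  genes <- unique(regulon$gene)
  role <- annotation[genes]
  role[is.na(role)] <- "none"
  lfc <- de$log2FoldChange[match(genes, de$feature)]
  dir <- classify_target_direction(lfc)
  counted <- role != "none" & !is.na(dir)
  driver_tally(
    UONC = sum(counted & role == "oncogene" & dir == "up"),
    DTSG = sum(counted & role == "tsg" & dir == "down"),
    DONC = sum(counted & role == "oncogene" & dir == "down"),
    UTSG = sum(counted & role == "tsg" & dir == "up"),
    ONCTSG = sum(counted & role == "dual")
  )
}

#' Oncogenic Activity of a regulator
#'
#' From a driver tally, the oncogenic effect is
#' `Oe = (UONC + DTSG) - ONCTSG`, the anti-oncogenic effect is
#' `Ae = (DONC + UTSG) - ONCTSG`, and the Oncogenic Activity is their
#' difference relative to the total number of driver targets,
#' `OA = (Oe - Ae) / T`. Dual-role genes cancel in `Oe - Ae`, so
#' `OA` always lies in \[-1, 1\]. With no driver targets (`T = 0`) the
#' score is undefined and flagged.
#'
#' @param tally a [driver_tally()].
#' @return list with `Oe`, `Ae`, `OA` (NA when undefined) and `defined`.
#' @export
oncogenic_activity <- function(tally) {
  stopifnot(inherits(tally, "driver_tally"))
  Oe <- (tally$UONC + tally$DTSG) - tally$ONCTSG
  Ae <- (tally$DONC + tally$UTSG) - tally$ONCTSG
  if (tally$T == 0) {
    return(list(Oe = Oe, Ae = Ae, OA = NA_real_, defined = FALSE))
  }
  list(Oe = Oe, Ae = Ae, OA = (Oe - Ae) / tally$T, defined = TRUE)
}

#' Classify a regulator by its Oncogenic Activity
#'
#' `"oncogenic"` for OA > 0, `"suppressor"` for OA < 0, `"neutral"` for
#' OA = 0 or an undefined score (no driver targets).
#'
#' @param oa numeric vector of OA values (NA = undefined).
#' @return character vector of classes.
#' @export
classify_mmr <- function(oa) {
  out <- rep("neutral", length(oa))
  out[!is.na(oa) & oa > 0] <- "oncogenic"
  out[!is.na(oa) & oa < 0] <- "suppressor"
  out
}

#' Oncogenic Activity table for a set of regulons
#'
#' Applies [tally_driver_targets()] and [oncogenic_activity()] to every
#' regulon and assembles the reporting table. `OA` is the exact value;
#' `OA_2dp` is rounded to two decimals for tabulation.
#'
#' @param regulons named list of regulons (see [build_regulons()]).
#' @param annotation driver annotation (see [tally_driver_targets()]).
#' @param de tumor-vs-normal mRNA DE table.
#' @return data frame with one row per regulator: tallies, `Oe`, `Ae`,
#'   `T`, `OA`, `OA_2dp` and `class`.
#' @export
oncogenic_activity_table <- function(regulons, annotation, de) {
  rows <- lapply(names(regulons), function(id) {
    tl <- tally_driver_targets(regulons[[id]], annotation, de)
    oa <- oncogenic_activity(tl)
    data.frame(mirna = id, UONC = tl$UONC, DTSG = tl$DTSG, DONC = tl$DONC,
               UTSG = tl$UTSG, ONCTSG = tl$ONCTSG, T = tl$T, Oe = oa$Oe,
               Ae = oa$Ae, OA = oa$OA, OA_2dp = round(oa$OA, 2),
               class = classify_mmr(oa$OA), stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  if (is.null(out)) {
    out <- data.frame(mirna = character(0), UONC = integer(0),
                      DTSG = integer(0), DONC = integer(0),
                      UTSG = integer(0), ONCTSG = integer(0),
                      T = integer(0), Oe = integer(0), Ae = integer(0),
                      OA = numeric(0), OA_2dp = numeric(0),
                      class = character(0))
  }
  rownames(out) <- NULL
  out
}
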