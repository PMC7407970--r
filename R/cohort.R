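#' Cohort generator configuration
#'
#' Describes a synthetic tumor/normal cohort with planted ground truth.
#' Counts are negative-binomial in the mean/size parameterization
#' (`size = 1 / dispersion`, so the variance is
#' `mu + dispersion * mu^2`). Planted miRNAs are upregulated in tumors
#' with a log2 shift of `lambda = stage_trend * stage + activity_sd * u`
#' (stage coded 1-4, `u ~ N(0, 1)` per tumor). Each planted edge shifts
#' its target gene's log2 mean in tumors by `sign * effect_size * z`,
#' where `z` is the regulator's z-score - its log2 elevation
#' standardized by the population moments of `lambda` - offset by +1,
#' so the planted regulator sits on average one s.d. above its
#' normal-tissue level and its targets track both its stage trend and
#' its per-tumor activity. Survival follows an exponential
#' proportional-hazards model with log-hazard
#' `survival_beta * mean(z)` over the planted regulators.
#'
#' Defaults describe the package's reference benchmark scale (a
#' desk-size stand-in for a large public tumor cohort): 300 tumors, 100 normals,
#' BRCA-like stage frequencies, moderate overdispersion 0.1 and 30%
#' lognormal library-size spread.
#'
#' @param n_tumor,n_normal sample counts (> 0).
#' @param n_mirna,n_mrna feature counts (> 0). Feature ids are
#'   `mir-001`, ... and `g0001`, ....
#' @param stage_probs stage I-IV probabilities, summing to 1.
#' @param planted_mmr_ids miRNA ids planted as upregulated master
#'   regulators.
#' @param planted_edges data frame (`mirna`, `gene`, `sign`, `effect`)
#'   of regulatory edges; `sign` in `c(-1, 1)`, `effect` the log2 shift
#'   per unit regulator z-score. Regulator miRNAs must be planted.
#' @param mirna_base_mean,mrna_base_mean baseline NB means.
#' @param dispersion NB dispersion (inverse of the `size` parameter).
#' @param stage_trend log2 increment per stage for planted miRNAs.
#' @param activity_sd s.d. of the regulator activity term on the miRNA
#'   log2 scale (within-tumor coupling noise).
#' @param libsize_lognormal_sd lognormal s.d. of library-size factors.
#' @param survival_beta log-hazard per unit regulator z-score.
#' @param censor_rate approximate censoring fraction in \[0, 1).
#' @param driver_roles optional named character vector of driver roles
#'   (`oncogene`, `tsg`, `dual`, `none`) per gene; unlisted genes are
#'   `none`.
#' @param seed integer RNG seed (required).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumor = 300, n_normal = 100, n_mirna = 10,
                          n_mrna = 200,
                          stage_probs = c(0.20, 0.55, 0.20, 0.05),
                          planted_mmr_ids = character(0),
                          planted_edges = NULL,
                          mirna_base_mean = 500, mrna_base_mean = 300,
                          dispersion = 0.1, stage_trend = 0.5,
                          activity_sd = 0.5,
                          libsize_lognormal_sd = 0.3,
                          survival_beta = 0.5, censor_rate = 0.7,
                          driver_roles = NULL, seed) {
  if (missing(seed)) stop("seed is required")
  cfg <- list(
    n_tumor = n_tumor, n_normal = n_normal, n_mirna = n_mirna,
    n_mrna = n_mrna, stage_probs = stage_probs,
    planted_mmr_ids = planted_mmr_ids, planted_edges = planted_edges,
    mirna_base_mean = mirna_base_mean, mrna_base_mean = mrna_base_mean,
    dispersion = dispersion, stage_trend = stage_trend,
    activity_sd = activity_sd,
    libsize_lognormal_sd = libsize_lognormal_sd,
    survival_beta = survival_beta, censor_rate = censor_rate,
    driver_roles = driver_roles, seed = as.integer(seed)
  )
  cfg$mirna_ids <- sprintf("mir-%03d", seq_len(n_mirna))
  cfg$gene_ids <- sprintf("g%04d", seq_len(n_mrna))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  dims <- c(cfg$n_tumor, cfg$n_normal, cfg$n_mirna, cfg$n_mrna)
  if (any(dims <= 0)) stop("all dimensions must be positive")
  if (length(cfg$stage_probs) != 4 ||
      abs(sum(cfg$stage_probs) - 1) > 1e-9 || any(cfg$stage_probs < 0)) {
    stop("stage_probs must be a 4-vector of probabilities summing to 1")
  }
  if (cfg$mirna_base_mean <= 0 || cfg$mrna_base_mean <= 0 ||
      cfg$dispersion <= 0) {
    stop("base means and dispersion must be positive")
  }
  if (cfg$libsize_lognormal_sd < 0) stop("libsize_lognormal_sd must be >= 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    stop("censor_rate must lie in [0, 1)")
  }
  if (!all(cfg$planted_mmr_ids %in% cfg$mirna_ids)) {
    stop("planted_mmr_ids reference undeclared miRNAs")
  }
  pe <- cfg$planted_edges
  if (!is.null(pe) && nrow(pe) > 0) {
    if (!all(pe$mirna %in% cfg$planted_mmr_ids)) {
      stop("planted edges must originate from planted miRNAs")
    }
    if (!all(pe$gene %in% cfg$gene_ids)) {
      stop("planted edges reference undeclared genes")
    }
    if (!all(pe$sign %in% c(-1, 1))) stop("edge signs must be -1 or +1")
  }
  invisible(cfg)
}

#' Reference benchmark configuration
#'
#' The package's standard planted-truth benchmark: 10 miRNAs and 200
#' genes over 300 tumors and 100 normals; miRNAs `mir-001`..`mir-005`
#' are planted master regulators, each repressing a disjoint block of
#' 20 genes with effect size 1.5 and a per-stage log2 trend of 1.0 (so
#' even stage-I tumors clear the +0.5 fold-change gate in truth).
#' Repressed targets of `mir-001`..`mir-003` are annotated as tumor
#' suppressors and those of `mir-004`/`mir-005` as oncogenes, so the
#' first group is truly oncogenic (OA = +1) and the second truly
#' suppressive (OA = -1); a few dual/decoy drivers sit among the
#' untargeted genes.
#'
#' @param seed integer RNG seed.
#' @return a [cohort_config()].
#' @export
benchmark_cohort_config <- function(seed) {
  planted <- sprintf("mir-%03d", 1:5)
  edges <- do.call(rbind, lapply(1:5, function(k) {
    data.frame(mirna = planted[k],
               gene = sprintf("g%04d", ((k - 1) * 20 + 1):(k * 20)),
               sign = -1, effect = 1.5, stringsAsFactors = FALSE)
  }))
  roles <- c(
    stats::setNames(rep("tsg", 60), sprintf("g%04d", 1:60)),
    stats::setNames(rep("oncogene", 40), sprintf("g%04d", 61:100)),
    stats::setNames(rep("dual", 5), sprintf("g%04d", 101:105)),
    stats::setNames(rep("oncogene", 10), sprintf("g%04d", 106:115)),
    stats::setNames(rep("tsg", 10), sprintf("g%04d", 116:125))
  )
  cohort_config(
    n_tumor = 300, n_normal = 100, n_mirna = 10, n_mrna = 200,
    planted_mmr_ids = planted, planted_edges = edges,
    stage_trend = 1.0, driver_roles = roles, seed = seed
  )
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws the full cohort described by a [cohort_config()]: miRNA and
#' mRNA count matrices (features x samples), sample metadata (condition,
#' stage, survival, clinical covariates) and the serialized ground
#' truth. Identical configs (including seed) give bit-identical output.
#'
#' @param config a [cohort_config()].
#' @return list with `mirna_counts`, `mrna_counts`, `metadata`, `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed)
  nt <- config$n_tumor; nn <- config$n_normal; n <- nt + nn
  sample_ids <- c(sprintf("T%04d", seq_len(nt)), sprintf("N%04d", seq_len(nn)))
  is_tumor <- c(rep(TRUE, nt), rep(FALSE, nn))

  stage_num <- sample(1:4, nt, replace = TRUE, prob = config$stage_probs)
  libf <- stats::rlnorm(n, 0, config$libsize_lognormal_sd)
  age <- pmin(pmax(round(stats::rnorm(n, 58, 12)), 25), 90)
  er <- ifelse(is_tumor, stats::rbinom(n, 1, 0.75), NA_integer_)
  pr <- ifelse(is_tumor, stats::rbinom(n, 1, 0.65), NA_integer_)

  planted <- config$planted_mmr_ids
  u <- matrix(stats::rnorm(length(planted) * nt), nrow = length(planted),
              ncol = nt, dimnames = list(planted, NULL))

  # planted log2 elevation and the regulator z-score derived from it
  # (standardized by population moments; +1 offset = one s.d. above the
  # normal-tissue level)
  lam <- config$stage_trend *
    matrix(rep(stage_num, length.out = length(planted) * nt),
           nrow = length(planted), ncol = nt, byrow = TRUE) +
    config$activity_sd * u
  mean_stage <- sum(config$stage_probs * (1:4))
  var_stage <- sum(config$stage_probs * (1:4)^2) - mean_stage^2
  sd_lam <- sqrt(config$stage_trend^2 * var_stage + config$activity_sd^2)
  z <- if (sd_lam > 0) {
    (lam - config$stage_trend * mean_stage) / sd_lam + 1
  } else {
    lam * 0 + 1
  }
  rownames(z) <- planted

  # miRNA log2 means
  l2m <- matrix(log2(config$mirna_base_mean), config$n_mirna, n,
                dimnames = list(config$mirna_ids, sample_ids))
  if (length(planted) > 0 && nt > 0) {
    l2m[planted, seq_len(nt)] <- l2m[planted, seq_len(nt)] + lam
  }
  mu_mirna <- sweep(2^l2m, 2, libf, "*")
  mirna_counts <- matrix(
    stats::rnbinom(length(mu_mirna), mu = mu_mirna,
                   size = 1 / config$dispersion),
    nrow = config$n_mirna, dimnames = dimnames(l2m))

  # mRNA log2 means
  l2g <- matrix(log2(config$mrna_base_mean), config$n_mrna, n,
                dimnames = list(config$gene_ids, sample_ids))
  pe <- config$planted_edges
  true_lfc_gene <- stats::setNames(rep(0, config$n_mrna), config$gene_ids)
  if (!is.null(pe) && nrow(pe) > 0 && nt > 0) {
    for (k in seq_len(nrow(pe))) {
      l2g[pe$gene[k], seq_len(nt)] <-
        l2g[pe$gene[k], seq_len(nt)] +
        pe$sign[k] * pe$effect[k] * z[pe$mirna[k], ]
      true_lfc_gene[pe$gene[k]] <-
        true_lfc_gene[pe$gene[k]] + pe$sign[k] * pe$effect[k]
    }
  }
  mu_mrna <- sweep(2^l2g, 2, libf, "*")
  mrna_counts <- matrix(
    stats::rnbinom(length(mu_mrna), mu = mu_mrna,
                   size = 1 / config$dispersion),
    nrow = config$n_mrna, dimnames = dimnames(l2g))

  # survival: exponential PH, baseline median 60 time units
  rate0 <- log(2) / 60
  zbar <- if (length(planted) > 0) colMeans(z) else rep(0, nt)
  t_event <- stats::rexp(nt, rate0 * exp(config$survival_beta * zbar))
  if (config$censor_rate > 0) {
    rate_c <- rate0 * config$censor_rate / (1 - config$censor_rate)
    t_cens <- stats::rexp(nt, rate_c)
  } else {
    t_cens <- rep(Inf, nt)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  metadata <- data.frame(
    sample_id = sample_ids,
    condition = ifelse(is_tumor, "tumor", "normal"),
    stage = c(c("I", "II", "III", "IV")[stage_num], rep(NA, nn)),
    time = c(round(time, 3), rep(NA, nn)),
    event = c(event, rep(NA_integer_, nn)),
    age = age,
    er_status = er,
    pr_status = pr,
    stringsAsFactors = FALSE
  )

  roles <- stats::setNames(rep("none", config$n_mrna), config$gene_ids)
  if (!is.null(config$driver_roles)) {
    hit <- intersect(names(config$driver_roles), config$gene_ids)
    roles[hit] <- config$driver_roles[hit]
  }
  true_lfc_mirna <- stats::setNames(rep(0, config$n_mirna), config$mirna_ids)
  true_lfc_mirna[planted] <- config$stage_trend * mean_stage

  truth <- structure(list(
    planted_mmr_ids = planted,
    planted_edges = if (is.null(pe)) {
      data.frame(mirna = character(0), gene = character(0),
                 sign = numeric(0), effect = numeric(0))
    } else pe,
    driver_roles = roles,
    true_lfc_mirna = true_lfc_mirna,
    true_lfc_gene = true_lfc_gene,
    mirna_ids = config$mirna_ids,
    gene_ids = config$gene_ids
  ), class = "cohort_truth")

  list(mirna_counts = mirna_counts, mrna_counts = mrna_counts,
       metadata = metadata, truth = truth)
}

#' Generate mock target-prediction databases
#'
#' Each database holds a `recall` fraction of the true planted edges
#' (independent Bernoulli draws) plus uniformly drawn decoy pairs (from
#' the non-true miRNA x gene pairs, without replacement) so that the
#' stated `precision` holds in expectation.
#'
#' @param truth a `cohort_truth` (or any list with `planted_edges`,
#'   `mirna_ids`, `gene_ids`).
#' @param n_dbs number of databases.
#' @param recall,precision per-database true-edge recall and expected
#'   precision, both in (0, 1\].
#' @param seed integer RNG seed.
#' @return list with `databases` (named list of `mirna`/`gene` edge
#'   frames) and `union` (their union).
#' @export
generate_target_databases <- function(truth, n_dbs = 3, recall = 0.8,
                                      precision = 0.25, seed = 1) {
  if (recall <= 0 || recall > 1 || precision <= 0 || precision > 1) {
    stop("recall and precision must lie in (0, 1]")
  }
  true_edges <- truth$planted_edges
  if (nrow(true_edges) == 0 && precision < 1) {
    stop("cannot build decoys for an empty true edge set with precision < 1")
  }
  all_pairs <- expand.grid(mirna = truth$mirna_ids, gene = truth$gene_ids,
                           stringsAsFactors = FALSE)
  true_key <- paste(true_edges$mirna, true_edges$gene)
  decoy_pool <- all_pairs[!(paste(all_pairs$mirna, all_pairs$gene) %in%
                              true_key), , drop = FALSE]
  set.seed(seed)
  dbs <- lapply(seq_len(n_dbs), function(d) {
    take <- stats::runif(nrow(true_edges)) <= recall
    kept <- true_edges[take, c("mirna", "gene"), drop = FALSE]
    n_decoy <- round(nrow(kept) * (1 - precision) / precision)
    n_decoy <- min(n_decoy, nrow(decoy_pool))
    decoys <- decoy_pool[sample.int(nrow(decoy_pool), n_decoy), ,
                         drop = FALSE]
    out <- rbind(kept, decoys)
    rownames(out) <- NULL
    out
  })
  names(dbs) <- paste0("db", seq_len(n_dbs))
  uni <- unique(do.call(rbind, dbs))
  rownames(uni) <- NULL
  list(databases = dbs, union = uni)
}

#' Generate a mock driver-gene annotation
#'
#' Assigns roles to genes in a seeded random order: `round(frac * n)`
#' genes per role (oncogene, then tsg, then dual - the documented
#' deterministic rounding rule), remaining genes `none`.
#'
#' @param genes character vector of gene ids.
#' @param frac_onc,frac_tsg,frac_dual role fractions, summing to <= 1.
#' @param seed integer RNG seed.
#' @return data frame with columns `gene`, `role`.
#' @export
generate_driver_annotation <- function(genes, frac_onc = 0.1,
                                       frac_tsg = 0.1, frac_dual = 0.05,
                                       seed = 1) {
  fr <- c(frac_onc, frac_tsg, frac_dual)
  if (any(fr < 0) || sum(fr) > 1) {
    stop("role fractions must be non-negative and sum to at most 1")
  }
  n <- length(genes)
  counts <- round(fr * n)
  while (sum(counts) > n) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1
  set.seed(seed)
  perm <- sample(genes)
  role <- rep("none", n)
  pos <- 0
  for (i in 1:3) {
    if (counts[i] > 0) {
      role[(pos + 1):(pos + counts[i])] <- c("oncogene", "tsg", "dual")[i]
      pos <- pos + counts[i]
    }
  }
  out <- data.frame(gene = perm, role = role, stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Write a generated cohort to disk
#'
#' Serializes counts, metadata, planted edges, driver roles and the
#' remaining ground truth (JSON) as plain text into `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_tsv(cohort$mirna_counts, file.path(dir, "counts_mirna.tsv"))
  write_counts_tsv(cohort$mrna_counts, file.path(dir, "counts_mrna.tsv"))
  write_tsv_table(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_tsv_table(cohort$truth$planted_edges,
                  file.path(dir, "truth_edges.tsv"))
  write_tsv_table(
    data.frame(gene = names(cohort$truth$driver_roles),
               role = unname(cohort$truth$driver_roles)),
    file.path(dir, "truth_driver_roles.tsv"))
  jsonlite::write_json(
    list(planted_mmr_ids = cohort$truth$planted_mmr_ids,
         true_lfc_mirna = as.list(cohort$truth$true_lfc_mirna),
         true_lfc_gene = as.list(cohort$truth$true_lfc_gene)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
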