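# A deliberately small simulated world so end-to-end paths stay fast:
# two planted regulators (one repressing TSGs, one repressing
# oncogenes) among six miRNAs.
tiny_pipeline_config <- function(seed) {
  planted <- c("mir-001", "mir-002")
  edges <- rbind(
    data.frame(mirna = "mir-001", gene = sprintf("g%04d", 1:10),
               sign = -1, effect = 1.5),
    data.frame(mirna = "mir-002", gene = sprintf("g%04d", 11:20),
               sign = -1, effect = 1.5))
  roles <- c(stats::setNames(rep("tsg", 10), sprintf("g%04d", 1:10)),
             stats::setNames(rep("oncogene", 10), sprintf("g%04d", 11:20)))
  sim <- cohort_config(n_tumor = 120, n_normal = 60, n_mirna = 6,
                       n_mrna = 60, planted_mmr_ids = planted,
                       planted_edges = edges, stage_trend = 1.0,
                       driver_roles = roles, survival_beta = 0.8,
                       censor_rate = 0.4, seed = seed)
  pipeline_config(simulate = sim, n_boot = 5, mi_null = 300,
                  nes_null = 300, min_regulon = 3,
                  db = list(n_dbs = 2, recall = 0.9, precision = 0.5),
                  seed = seed)
}

# The reference planted-truth benchmark run once per seed: simulate,
# pooled mRNA DE, MI network over all candidate miRNAs, MMR calls.
# Used by the acceptance suite; memoized because two criteria share it.
run_benchmark_seed <- function(s) {
  ch <- generate_cohort(benchmark_cohort_config(seed = s))
  meta <- ch$metadata
  tum <- meta$sample_id[meta$condition == "tumor"]
  cond <- factor(meta$condition, levels = c("normal", "tumor"))
  sf <- depth_factors(rbind(ch$mirna_counts, ch$mrna_counts))
  de_mrna <- nb_differential_expression(ch$mrna_counts, cond,
                                        factors = sf)
  mv <- vst_transform(ch$mirna_counts, sf)
  gv <- vst_transform(ch$mrna_counts, sf)
  thr <- mi_threshold(length(tum), p_value = 1e-4, n_null = 1000,
                      seed = 10000 + s)
  net <- bootstrap_consensus(mv[, tum], gv[, tum], n_boot = 20,
                             threshold = thr, seed = 20000 + s)
  mmr <- mmr_analysis(net, de_mrna, min_size = 3, n_null = 1000,
                      seed = 30000 + s)
  list(truth = ch$truth, de_mrna = de_mrna, network = net, mmr = mmr)
}

benchmark_runs <- local({
  cache <- list()
  function(seeds = 1:5) {
    for (s in seeds) {
      key <- as.character(s)
      if (is.null(cache[[key]])) cache[[key]] <<- run_benchmark_seed(s)
    }
    cache[as.character(seeds)]
  }
})
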