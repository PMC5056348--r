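#' Seeded end-to-end recovery benchmark of the DMR caller
#'
#' For each seed, simulates a genome and depth matrix under `config` (with
#' the seed substituted), runs coverage filtering, normalization and
#' [call_dmrs()], and scores the calls against the planted truth with
#' [dmr_recovery()].  This is the operating-characteristic harness: recall
#' and empirical FDR under planted effects, and the false-call rate under
#' the null (`config` with `n_dmrs = 0`).
#'
#' @param seeds Integer vector; one full simulation + call per seed.
#' @param config Template [sim_config()] (its `seed` is replaced per run).
#' @param params Template [dmr_params()] (its `seed` is replaced per run).
#' @return data.frame with one row per seed: n_sites, n_truth, n_called,
#'   n_recovered, recall (NA for null runs), n_false and empirical_fdr.
#' @export
dmr_benchmark <- function(seeds, config = sim_config(),
                          params = dmr_params()) {
  rows <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    prm <- params; prm$seed <- as.integer(s)
    gm <- make_genome(cfg)
    truth <- plant_dmrs(gm, cfg)
    dm <- normalize_depths(filter_low_coverage(simulate_depths(gm, truth, cfg)))
    res <- suppressWarnings(call_dmrs(dm, prm))
    rec <- dmr_recovery(res, truth)
    data.frame(seed = s, n_sites = nrow(dm$depth), n_truth = rec$n_truth,
               n_called = rec$n_called, n_recovered = rec$n_recovered,
               recall = rec$recall, n_false = rec$n_false,
               empirical_fdr = rec$empirical_fdr)
  })
  do.call(rbind, rows)
}
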