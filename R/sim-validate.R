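# Generators for the validation-module inputs.

#' Simulate a bisulfite-sequencing clone matrix
#'
#' Bernoulli methylation calls per (clone, site); mirrors the standard BSP
#' design of ten sequenced subclones per region.
#'
#' @param n_clones Number of subclones (rows; default 10).
#' @param n_sites Number of CpG sites (columns).
#' @param site_methylation_probs Per-site methylation probability, recycled
#'   to `n_sites`; all values in \[0,1\].
#' @param seed RNG seed.
#' @return Binary matrix (clones x sites) with site column names.
#' @export
simulate_clone_matrix <- function(n_clones = 10L, n_sites,
                                  site_methylation_probs, seed = 1L) {
  probs <- rep_len(site_methylation_probs, n_sites)
  if (any(probs < 0) || any(probs > 1))
    stop("methylation probabilities must lie in [0,1]")
  with_seed(seed, {
    m <- matrix(rbinom(n_clones * n_sites, 1L, rep(probs, each = n_clones)),
                nrow = n_clones, ncol = n_sites)
    colnames(m) <- sprintf("CpG_%02d", seq_len(n_sites))
    m
  })
}

#' Simulate a qPCR Ct table
#'
#' Builds a long-format Ct table for two groups where group 1 expresses
#' each target at `true_fold_changes` times the calibrator (group 2)
#' level: Ct = baseline - log2(expression) + Gaussian noise.  Reference
#' genes are expressed equally in both groups, so [ddct()] recovers the
#' configured fold changes (exactly when `ct_noise_sd = 0`).
#'
#' @param true_fold_changes Named numeric vector (gene -> fold change > 0).
#' @param ct_noise_sd SD of per-well Gaussian Ct noise.
#' @param n_per_group Biological replicates per group (default 3).
#' @param n_tech_reps Technical replicates per well (default 3).
#' @param reference_genes Internal-control gene names.
#' @param group_names Length-2 group labels (group 2 is the calibrator).
#' @param seed RNG seed.
#' @return Long data.frame (`sample`, `group`, `gene`, `ct`).
#' @export
simulate_qpcr <- function(true_fold_changes, ct_noise_sd = 0.1,
                          n_per_group = 3L, n_tech_reps = 3L,
                          reference_genes = c("ACTB", "TBP", "TOP2B"),
                          group_names = c("g1", "g2"), seed = 1L) {
  if (is.null(names(true_fold_changes)))
    names(true_fold_changes) <- paste0("target", seq_along(true_fold_changes))
  if (any(true_fold_changes <= 0))
    stop("fold changes must be positive")
  with_seed(seed, {
    ref_base <- setNames(18 + seq_along(reference_genes), reference_genes)
    tgt_base <- setNames(22 + seq_along(true_fold_changes),
                         names(true_fold_changes))
    rows <- list()
    for (gi in 1:2) {
      for (s in seq_len(n_per_group)) {
        smp <- paste0(group_names[gi], "_", s)
        for (g in reference_genes) {
          ct <- ref_base[g] + rnorm(n_tech_reps, 0, ct_noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = smp, group = group_names[gi], gene = g, ct = ct)
        }
        for (g in names(true_fold_changes)) {
          expr <- if (gi == 1) true_fold_changes[g] else 1
          ct <- tgt_base[g] - log2(expr) + rnorm(n_tech_reps, 0, ct_noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = smp, group = group_names[gi], gene = g, ct = ct)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
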