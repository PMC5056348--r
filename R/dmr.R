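# Seed-and-extend DMR calling with permutation-based BH FDR.

P_FLOOR <- 1e-300  # -log10 region statistic floor for underflowing p-values

#' DMR calling parameters
#'
#' @param seed_alpha Per-CpG significance level defining seed (highly
#'   variable) sites; default 0.01.
#' @param bartlett_alpha Bartlett gate level routing each site to the
#'   parametric (p > alpha) or nonparametric test; default 0.05.
#' @param join_window_bp Maximum distance from the current region edge at
#'   which the next downstream significant CpG is absorbed; default 200.
#' @param max_gap_bp Window within which a non-significant CpG terminates
#'   extension; default 2000.  Because any non-significant or
#'   >`join_window_bp`-distant next CpG ends the region either way, this
#'   parameter does not change the called regions; it is kept for
#'   completeness of the extension rule.
#' @param min_sig_cpgs Minimum significant CpGs for a region to be reported
#'   (default 5).
#' @param n_permutations Group-relabeling draws for the empirical region
#'   null (default 1000).
#' @param fdr BH-adjusted significance level for reported DMRs
#'   (default 0.01).
#' @param seed RNG seed for the permutation draws.
#' @return An object of class `dmr_params`.
#' @export
dmr_params <- function(seed_alpha = 0.01, bartlett_alpha = 0.05,
                       join_window_bp = 200L, max_gap_bp = 2000L,
                       min_sig_cpgs = 5L, n_permutations = 1000L,
                       fdr = 0.01, seed = 1L) {
  p <- list(seed_alpha = seed_alpha, bartlett_alpha = bartlett_alpha,
            join_window_bp = as.integer(join_window_bp),
            max_gap_bp = as.integer(max_gap_bp),
            min_sig_cpgs = as.integer(min_sig_cpgs),
            n_permutations = as.integer(n_permutations),
            fdr = fdr, seed = as.integer(seed))
  if (p$seed_alpha <= 0 || p$seed_alpha >= 1 ||
      p$bartlett_alpha <= 0 || p$bartlett_alpha >= 1)
    stop("alphas must lie strictly inside (0,1)")
  if (p$join_window_bp > p$max_gap_bp)
    stop("join_window_bp must not exceed max_gap_bp")
  if (p$min_sig_cpgs < 1) stop("min_sig_cpgs must be >= 1")
  if (p$n_permutations < 1) stop("n_permutations must be >= 1")
  if (p$fdr <= 0 || p$fdr > 1) stop("fdr must lie in (0,1]")
  class(p) <- "dmr_params"
  p
}

#' Seed CpG indices
#'
#' @param site_results data.frame from [site_tests()] (or any frame with a
#'   `p` column in coordinate order).
#' @param params A [dmr_params()].
#' @return Integer indices (1-based, coordinate order) of sites with
#'   p < `seed_alpha`.
#' @export
find_seeds <- function(site_results, params = dmr_params()) {
  which(site_results$p < params$seed_alpha)
}

# Run decomposition shared by candidate_regions() and extend_region():
# maximal runs of consecutive significant CpGs on one chromosome with
# successive gaps <= join_window_bp.  Returns per-site run id (NA for
# non-significant sites).
.region_runs <- function(chrom, pos, p, params) {
  sig <- p < params$seed_alpha
  idx <- which(sig)
  if (length(idx) == 0) return(list(idx = idx, run = integer(0)))
  new_run <- c(TRUE,
               diff(idx) != 1L |
                 chrom[idx[-1]] != chrom[idx[-length(idx)]] |
                 (pos[idx[-1]] - pos[idx[-length(idx)]]) > params$join_window_bp)
  list(idx = idx, run = cumsum(new_run))
}

#' Candidate DMRs by seed extension
#'
#' Implements the seed-and-extend rule: starting from each seed CpG
#' (p < `seed_alpha`), the next downstream CpG is absorbed while it is
#' itself significant and within `join_window_bp` of the current region
#' edge; a non-significant CpG (the low-variance terminator, allowed within
#' `max_gap_bp`) or a larger gap ends the region.  Candidates grown from
#' different seeds that overlap are merged, so each reported region is the
#' maximal qualifying run; regions need at least `min_sig_cpgs` significant
#' CpGs.
#'
#' @param chrom,pos Site coordinates in (chrom, pos) order.
#' @param p Per-site p-values.
#' @param params A [dmr_params()].
#' @return data.frame with chrom, start, end (0-based half-open spanning
#'   first to last member dinucleotide), first/last site index, n_cpg,
#'   n_sig and the region statistic `stat` = sum(-log10 p) over members.
#' @export
candidate_regions <- function(chrom, pos, p, params = dmr_params()) {
  rr <- .region_runs(chrom, pos, p, params)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), first = integer(0), last = integer(0),
                      n_cpg = integer(0), n_sig = integer(0),
                      stat = numeric(0), stringsAsFactors = FALSE)
  if (length(rr$idx) == 0) return(empty)
  len <- tabulate(rr$run)
  keep_run <- which(len >= params$min_sig_cpgs)
  if (length(keep_run) == 0) return(empty)
  first <- vapply(keep_run, function(r) rr$idx[match(r, rr$run)], integer(1))
  last <- first + len[keep_run] - 1L  # members are consecutive site indices
  stat <- vapply(seq_along(keep_run), function(i) {
    sum(-log10(pmax(p[first[i]:last[i]], P_FLOOR)))
  }, numeric(1))
  data.frame(
    chrom = chrom[first], start = pos[first], end = pos[last] + 2L,
    first = first, last = last,
    n_cpg = last - first + 1L, n_sig = len[keep_run],
    stat = stat, stringsAsFactors = FALSE
  )
}

#' Extend a single seed CpG into its candidate region
#'
#' Returns the merged maximal region containing `seed` (equivalently, what
#' [candidate_regions()] reports for the run this seed belongs to), or a
#' zero-row frame when the run holds fewer than `min_sig_cpgs` significant
#' CpGs.
#'
#' @param seed 1-based site index of a significant CpG.
#' @inheritParams candidate_regions
#' @return One-row (or empty) data.frame in the [candidate_regions()]
#'   layout.
#' @export
extend_region <- function(seed, chrom, pos, p, params = dmr_params()) {
  if (!(p[seed] < params$seed_alpha))
    stop("seed site is not significant at seed_alpha")
  cands <- candidate_regions(chrom, pos, p, params)
  cands[cands$first <= seed & cands$last >= seed, , drop = FALSE]
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvals Numeric vector of p-values in \[0,1\].
#' @return q-values: `q_(i) = min_{j >= i} p_(j) * n / j` in sorted order,
#'   mapped back to the input order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0,1]")
  n <- length(pvals)
  o <- order(pvals)
  q_sorted <- pmin(1, rev(cummin(rev(pvals[o] * n / seq_len(n)))))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Distinct balanced group relabelings of the depth matrix columns, as a
# list of group-1 column index vectors.  The identity labeling is excluded;
# for equal group sizes a labeling and its complement give identical
# p-vectors, so only the member containing column 1 is kept.
.null_labelings <- function(g1, g2) {
  n1 <- length(g1); N <- n1 + length(g2)
  combs <- combn(N, n1)
  keep <- rep(TRUE, ncol(combs))
  if (n1 == length(g2)) keep <- combs[1, ] == 1L
  ident1 <- sort(g1); ident2 <- sort(g2)  # identity up to group swap
  is_ident <- vapply(seq_len(ncol(combs)), function(i) {
    identical(combs[, i], ident1) ||
      (n1 == length(g2) && identical(combs[, i], ident2))
  }, logical(1))
  sel <- which(keep & !is_ident)
  lapply(sel, function(i) combs[, i])
}

#' Permutation-based empirical region p-values with BH correction
#'
#' The null distribution of the region statistic (sum over member CpGs of
#' -log10 site p) is built by re-running the site tests and seed extension
#' under permuted group labels: each of `n_permutations` draws combines a
#' distinct non-identity balanced relabeling of the samples with a random
#' circular shift of the site-to-depth assignment, and contributes the
#' maximum candidate-region statistic of that draw (0 when no candidate
#' forms).  With 3 vs 3 samples only 9 distinct non-identity relabelings
#' exist (after complement deduplication), so the shifts provide the
#' additional randomization.  Empirical region p =
#' (1 + #\{null >= observed\}) / (n_permutations + 1); q-values are BH
#' step-up over all candidates.
#'
#' @param candidates data.frame from [candidate_regions()] on the observed
#'   labels.
#' @param dm The [depth_matrix()] the candidates were called on.
#' @param params A [dmr_params()].
#' @return `candidates` with `region_p` and `q` columns appended; attribute
#'   `perm_meta` records the scheme (labelings used, draws, seed).
#' @export
permutation_fdr <- function(candidates, dm, params = dmr_params()) {
  gc <- group_columns(dm)
  labs <- .null_labelings(gc$g1, gc$g2)
  n_sites <- nrow(dm$depth)
  all_cols <- seq_len(ncol(dm$depth))
  pv <- lapply(labs, function(l) {
    site_tests(dm, bartlett_alpha = params$bartlett_alpha,
               g1 = l, g2 = setdiff(all_cols, l))$p
  })
  null_max <- with_seed(params$seed, {
    lab_idx <- sample.int(length(labs), params$n_permutations, replace = TRUE)
    shift <- floor(runif(params$n_permutations) * n_sites)
    vapply(seq_len(params$n_permutations), function(b) {
      rot <- ((seq_len(n_sites) - 1L + shift[b]) %% n_sites) + 1L
      cand <- candidate_regions(dm$chrom, dm$pos, pv[[lab_idx[b]]][rot], params)
      if (nrow(cand) == 0) 0 else max(cand$stat)
    }, numeric(1))
  })
  region_p <- vapply(candidates$stat, function(s) {
    (1 + sum(null_max >= s - 1e-12)) / (params$n_permutations + 1)
  }, numeric(1))
  out <- candidates
  out$region_p <- region_p
  out$q <- benjamini_hochberg(region_p)
  attr(out, "perm_meta") <- list(
    scheme = "non-identity balanced relabelings x circular site shifts, max region statistic per draw",
    n_labelings = length(labs),
    n_permutations = params$n_permutations,
    seed = params$seed
  )
  out
}

#' Call differentially methylated regions
#'
#' Orchestrates the full caller on a normalized, coverage-filtered depth
#' matrix: Bartlett-gated site tests, seed selection, seed extension into
#' candidate regions, and permutation-based empirical region p-values with
#' BH control.  Direction is "hyper" when the group-1 mean normalized depth
#' over member CpGs exceeds group 2's.
#'
#' @param dm A [depth_matrix()] (warns if not normalized).
#' @param params A [dmr_params()].
#' @return An object of class `dmr_result`: list with `dmrs` (called
#'   regions at q < `fdr`), `candidates` (all candidates with region_p/q),
#'   `sites` (per-site test results), `params`, `groups` and `perm_meta`.
#' @export
call_dmrs <- function(dm, params = dmr_params()) {
  gc <- group_columns(dm)
  if (length(gc$g1) < 2 || length(gc$g2) < 2)
    stop("fewer than 2 samples in a group")
  if (!dm$normalized)
    warning("calling DMRs on an unnormalized depth matrix")
  st <- site_tests(dm, bartlett_alpha = params$bartlett_alpha)
  n_comb <- choose(ncol(dm$depth), length(gc$g1))
  if (any(st$route == "nonparametric") && 2 / n_comb >= params$seed_alpha)
    warning("nonparametric route starved: the exact Mann-Whitney minimum ",
            "two-sided p (", signif(2 / n_comb, 3), ") cannot fall below ",
            "seed_alpha = ", params$seed_alpha, " at this sample size; ",
            "Bartlett-failing sites can never seed a DMR",
            call. = FALSE)
  cands <- candidate_regions(dm$chrom, dm$pos, st$p, params)
  cands <- permutation_fdr(cands, dm, params)
  if (nrow(cands) > 0) {
    mg <- t(vapply(seq_len(nrow(cands)), function(i) {
      rows <- cands$first[i]:cands$last[i]
      c(mean(dm$depth[rows, gc$g1]), mean(dm$depth[rows, gc$g2]))
    }, numeric(2)))
    cands$mean1 <- mg[, 1]; cands$mean2 <- mg[, 2]
    cands$direction <- ifelse(cands$mean1 > cands$mean2, "hyper", "hypo")
  } else {
    cands$mean1 <- cands$mean2 <- numeric(0)
    cands$direction <- character(0)
  }
  res <- list(
    dmrs = cands[cands$q < params$fdr, , drop = FALSE],
    candidates = cands,
    sites = st,
    params = params,
    groups = gc$labels,
    perm_meta = attr(cands, "perm_meta")
  )
  rownames(res$dmrs) <- NULL
  class(res) <- "dmr_result"
  res
}

#' @export
print.dmr_result <- function(x, ...) {
  cat("dmr_result:", nrow(x$dmrs), "DMRs at q <", x$params$fdr,
      "(", nrow(x$candidates), "candidates,", nrow(x$sites), "sites;",
      "group 1 =", x$groups[1], "vs group 2 =", x$groups[2], ")\n")
  invisible(x)
}

#' Compare called DMRs with a planted truth set
#'
#' @param result A `dmr_result` (or a data.frame of called regions with
#'   chrom/start/end/direction).
#' @param truth A `truth_set` from [plant_dmrs()].
#' @return Named list: `n_truth`, `n_called`, `n_recovered` (truth regions
#'   overlapped >= 1 bp by a call), `recall`, `n_false` (calls overlapping
#'   no truth region), `empirical_fdr` (0 when nothing is called), and
#'   `direction_accuracy` among recovering calls.
#' @export
dmr_recovery <- function(result, truth) {
  calls <- if (inherits(result, "dmr_result")) result$dmrs else result
  t_gr <- GenomicRanges::GRanges(truth$chrom,
                                 IRanges::IRanges(truth$start + 1L, truth$end))
  if (nrow(calls) == 0) {
    return(list(n_truth = nrow(truth), n_called = 0L, n_recovered = 0L,
                recall = if (nrow(truth) > 0) 0 else NA_real_,
                n_false = 0L, empirical_fdr = 0,
                direction_accuracy = NA_real_))
  }
  c_gr <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$start + 1L, calls$end))
  hits <- GenomicRanges::findOverlaps(c_gr, t_gr)
  recovered <- unique(S4Vectors::subjectHits(hits))
  false <- setdiff(seq_len(nrow(calls)), unique(S4Vectors::queryHits(hits)))
  dir_ok <- NA_real_
  if (length(hits) > 0)
    dir_ok <- mean(calls$direction[S4Vectors::queryHits(hits)] ==
                     truth$direction[S4Vectors::subjectHits(hits)])
  list(
    n_truth = nrow(truth), n_called = nrow(calls),
    n_recovered = length(recovered),
    recall = if (nrow(truth) > 0) length(recovered) / nrow(truth) else NA_real_,
    n_false = length(false),
    empirical_fdr = length(false) / nrow(calls),
    direction_accuracy = dir_ok
  )
}

#' Write called DMRs as BED6+ and TSV
#'
#' BED columns: chrom, start, end, name (DMR id), score
#' (-10*log10 q, capped at 1000), strand ('.'), then n_cpg, n_sig, group
#' means, direction, region_p, q.  The TSV twin carries a header.
#'
#' @param result A `dmr_result` or a DMR data.frame.
#' @param prefix Output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @return The two paths, invisibly.
#' @export
write_dmrs <- function(result, prefix) {
  calls <- if (inherits(result, "dmr_result")) result$dmrs else result
  score <- pmin(1000, round(-10 * log10(pmax(calls$q, 1e-100))))
  df <- data.frame(
    chrom = calls$chrom, start = calls$start, end = calls$end,
    name = sprintf("DMR_%04d", seq_len(nrow(calls))), score = score,
    strand = rep(".", nrow(calls)), n_cpg = calls$n_cpg, n_sig = calls$n_sig,
    mean1 = calls$mean1, mean2 = calls$mean2, direction = calls$direction,
    region_p = calls$region_p, q = calls$q, stringsAsFactors = FALSE
  )
  bed <- paste0(prefix, ".bed"); tsv <- paste0(prefix, ".tsv")
  write.table(df, bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed, tsv))
}

#' Read DMRs written by [write_dmrs()]
#'
#' @param path The `.tsv` twin (headered) path.
#' @return data.frame of DMR records.
#' @export
read_dmrs <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
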