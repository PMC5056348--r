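#' Plant ground-truth differentially methylated regions
#'
#' Selects `config$n_dmrs` non-overlapping runs of `dmr_n_cpg` consecutive
#' CpG sites that are CpG-dense (internal gaps <= `dmr_max_gap_bp`, span <=
#' `dmr_length_bp`) and assigns each a multiplicative group-1/group-2 depth
#' ratio: `dmr_effect` for hypermethylated regions, `1/dmr_effect` for
#' hypomethylated ones (fraction `dmr_hypo_fraction`).  Planted regions are
#' separated by at least `dmr_length_bp` so neighbouring truth regions
#' cannot merge during calling.
#'
#' @param genome A `genome_model` from [make_genome()].
#' @param config A [sim_config()].
#' @return A `truth_set`: data.frame with chrom, start, end (0-based
#'   half-open, spanning first to last member dinucleotide), n_cpg, effect
#'   (> 0, never 1) and direction ("hyper" iff effect > 1, in group 1).
#' @export
plant_dmrs <- function(genome, config) {
  validate_sim_config(config)
  sites <- genome$sites
  if (config$n_dmrs == 0L || nrow(sites) == 0L) {
    ts <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                     n_cpg = integer(0), effect = numeric(0),
                     direction = character(0))
    class(ts) <- c("truth_set", "data.frame")
    return(ts)
  }
  k <- config$dmr_n_cpg
  # candidate start indices: runs of k consecutive sites, dense and compact
  same_chrom <- c(sites$chrom[-1] == sites$chrom[-nrow(sites)], FALSE)
  gap_ok <- c(diff(sites$pos) <= config$dmr_max_gap_bp, FALSE) & same_chrom
  ok_run <- if (k == 1L) rep(TRUE, nrow(sites)) else {
    # gap_ok[i] says sites i,i+1 are joinable; need k-1 consecutive TRUEs
    cs <- cumsum(c(0L, as.integer(gap_ok)))
    idx <- seq_len(nrow(sites) - k + 1L)
    (cs[idx + k - 1L] - cs[idx]) == (k - 1L)
  }
  span_ok <- if (k == 1L) ok_run else {
    idx <- seq_len(nrow(sites) - k + 1L)
    (sites$pos[idx + k - 1L] + 2L - sites$pos[idx]) <= config$dmr_length_bp
  }
  cand <- which(ok_run & span_ok)
  with_seed(config$seed + 1L, {
    cand <- cand[sample.int(length(cand))]
    chosen <- integer(0)
    occupied_chrom <- character(0)
    occupied_lo <- occupied_hi <- integer(0)
    for (i in cand) {
      if (length(chosen) >= config$n_dmrs) break
      lo <- sites$pos[i] - config$dmr_length_bp
      hi <- sites$pos[i + k - 1L] + 2L + config$dmr_length_bp
      ch <- sites$chrom[i]
      clash <- any(occupied_chrom == ch & occupied_lo < hi & occupied_hi > lo)
      if (!clash) {
        chosen <- c(chosen, i)
        occupied_chrom <- c(occupied_chrom, ch)
        occupied_lo <- c(occupied_lo, lo)
        occupied_hi <- c(occupied_hi, hi)
      }
    }
    if (length(chosen) < config$n_dmrs)
      warning("only ", length(chosen), " of ", config$n_dmrs,
              " requested DMRs could be planted")
    chosen <- sort(chosen)
    n_hypo <- round(length(chosen) * config$dmr_hypo_fraction)
    dir_hypo <- rep(FALSE, length(chosen))
    if (n_hypo > 0) dir_hypo[sample.int(length(chosen), n_hypo)] <- TRUE
    ts <- data.frame(
      chrom = sites$chrom[chosen],
      start = sites$pos[chosen],
      end = sites$pos[chosen + k - 1L] + 2L,
      n_cpg = k,
      effect = ifelse(dir_hypo, 1 / config$dmr_effect, config$dmr_effect),
      direction = ifelse(dir_hypo, "hypo", "hyper"),
      stringsAsFactors = FALSE
    )
    class(ts) <- c("truth_set", "data.frame")
    ts
  })
}

#' Simulate per-CpG read depths for two groups
#'
#' Depth at CpG i in sample s is drawn from a negative binomial with mean
#' `baseline_mean * m_i * e_is` and dispersion `config$dispersion`
#' (variance mu + a*mu^2; Poisson when a = 0), where `m_i` is the optional
#' CpG-density enrichment multiplier (see `density_link` in [sim_config()])
#' and `e_is` is the truth-region effect for group-1 samples inside a
#' planted region (1 elsewhere and for all group-2 samples).
#'
#' @param genome A `genome_model`.
#' @param truth A `truth_set` from [plant_dmrs()] (may have zero rows).
#' @param config A [sim_config()].
#' @return A raw (unnormalized) [depth_matrix()] with integer depths.
#' @export
simulate_depths <- function(genome, truth, config) {
  validate_sim_config(config)
  sites <- genome$sites
  n_sites <- nrow(sites)
  n <- config$n_samples_per_group
  groups <- rep(config$group_names, each = n)
  samples <- paste0(rep(config$group_names, each = n), "_", rep(seq_len(n), 2))

  if (nrow(truth) > 0) {
    bad <- !(truth$chrom %in% names(genome$chrom_lengths)) |
      truth$end > genome$chrom_lengths[truth$chrom] | truth$start < 0
    if (any(bad))
      stop("truth region off-chromosome: ",
           paste(truth$chrom[bad], truth$start[bad], sep = ":", collapse = ", "))
  }

  # per-site mean multiplier from local CpG density (window-level)
  m <- rep(1, n_sites)
  if (config$density_link != 0 && n_sites > 0) {
    w <- genome$windows
    dens <- w$n_cpg / (w$end - w$start)
    key_w <- paste0(w$chrom, ":", (w$start %/% config$window_bp))
    key_s <- paste0(sites$chrom, ":", (sites$pos %/% config$window_bp))
    dens_s <- dens[match(key_s, key_w)]
    m <- (dens_s / mean(dens_s))^config$density_link
  }

  # effect per site for group-1 samples
  eff <- rep(1, n_sites)
  if (nrow(truth) > 0 && n_sites > 0) {
    for (r in seq_len(nrow(truth))) {
      inside <- sites$chrom == truth$chrom[r] &
        sites$pos >= truth$start[r] & sites$pos + 2L <= truth$end[r]
      eff[inside] <- truth$effect[r]
    }
  }

  with_seed(config$seed + 2L, {
    if (config$site_sd > 0)
      m <- m * exp(rnorm(n_sites, 0, config$site_sd) - config$site_sd^2 / 2)
    mu1 <- config$baseline_mean * m * eff
    mu2 <- config$baseline_mean * m
    draw <- function(mu) {
      if (config$dispersion == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    }
    depth <- matrix(0L, nrow = n_sites, ncol = 2L * n,
                    dimnames = list(NULL, samples))
    for (j in seq_len(n)) depth[, j] <- draw(mu1)
    for (j in seq_len(n)) depth[, n + j] <- draw(mu2)
    storage.mode(depth) <- "integer"
    depth_matrix(chrom = sites$chrom, pos = sites$pos, depth = depth,
                 groups = groups)
  })
}

#' Write / read a truth set as BED6+effect
#'
#' Columns: chrom, start, end, name, score (= n_cpg), strand ('.'), effect,
#' direction.
#'
#' @param truth A `truth_set`.
#' @param path File path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` a
#'   `truth_set`.
#' @export
write_truth <- function(truth, path) {
  df <- data.frame(
    chrom = truth$chrom, start = truth$start, end = truth$end,
    name = sprintf("truth_%04d", seq_len(nrow(truth))),
    score = truth$n_cpg, strand = ".",
    effect = truth$effect, direction = truth$direction
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand", "effect", "direction"))
  ts <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                   n_cpg = df$score, effect = df$effect,
                   direction = df$direction, stringsAsFactors = FALSE)
  class(ts) <- c("truth_set", "data.frame")
  ts
}
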