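# Independent brute-force oracles and small fixture builders.  Everything
# here is deliberately naive and separate from the package implementation.

# BH step-up computed directly from the definition on the sorted vector.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(1, min(p[o][i:n] * n / (i:n)))
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Maximal qualifying runs of significant CpGs, by direct scan: a run is a
# maximal stretch of consecutive sites that are all significant, on one
# chromosome, with successive gaps <= join_window; reported iff it holds at
# least min_sig significant CpGs.
runs_brute <- function(chrom, pos, p, seed_alpha = 0.01, join_window = 200,
                       min_sig = 5) {
  n <- length(p)
  sig <- p < seed_alpha
  out <- list()
  i <- 1
  while (i <= n) {
    if (!sig[i]) { i <- i + 1; next }
    j <- i
    while (j < n && sig[j + 1] && chrom[j + 1] == chrom[j] &&
           (pos[j + 1] - pos[j]) <= join_window) {
      j <- j + 1
    }
    if (sum(sig[i:j]) >= min_sig) {
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom[i], start = pos[i], end = pos[j] + 2L,
        first = i, last = j, n_sig = j - i + 1L
      )
    }
    i <- j + 1
  }
  if (length(out) == 0) {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               first = integer(0), last = integer(0), n_sig = integer(0))
  } else do.call(rbind, out)
}

# O(n*m) interval-overlap depth count: read [s,e) overlaps CpG [p,p+2)
# iff s < p + 2 and e > p.
overlap_brute <- function(reads, sites) {
  depth <- matrix(0L, nrow = nrow(sites),
                  ncol = length(unique(reads$sample)),
                  dimnames = list(NULL, sort(unique(reads$sample))))
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]
    hit <- reads$chrom == sites$chrom[i] & reads$start < p + 2 & reads$end > p
    if (any(hit)) {
      tab <- table(reads$sample[hit])
      depth[i, names(tab)] <- as.integer(tab)
    }
  }
  depth
}

# Textbook two-group Bartlett statistic, written out step by step.
bartlett_hand <- function(x, y) {
  k <- 2
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (N - k)
  num <- (N - k) * log(sp2) - ((n1 - 1) * log(var(x)) + (n2 - 1) * log(var(y)))
  C <- 1 + (1 / (n1 - 1) + 1 / (n2 - 1) - 1 / (N - k)) / (3 * (k - 1))
  pchisq(num / C, df = k - 1, lower.tail = FALSE)
}

# Pooled-variance t computed by hand.
t_hand <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(abs(tt), df = n1 + n2 - 2, lower.tail = FALSE)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# over the pooled values (mid-ranks), counting assignments at least as
# extreme as the observed split.
mw_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); N <- length(pooled)
  r <- rank(pooled)
  mu <- n1 * (N - n1) / 2
  u_of <- function(cols) sum(r[cols]) - n1 * (n1 + 1) / 2
  dev_obs <- abs(u_of(seq_len(n1)) - mu)
  combs <- combn(N, n1)
  devs <- apply(combs, 2, function(cols) abs(u_of(cols) - mu))
  mean(devs >= dev_obs - 1e-9)
}

# Minimal hand-built genome model for unit fixtures.
toy_genome <- function(chrom_lengths, sites) {
  wins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    data.frame(chrom = ch, start = 0L,
               end = as.integer(chrom_lengths[ch]),
               gc = 0.5, cpg_oe = 0.25,
               n_cpg = sum(sites$chrom == ch))
  }))
  structure(list(chrom_lengths = chrom_lengths, windows = wins,
                 sites = sites[order(sites$chrom, sites$pos), ]),
            class = "genome_model")
}

# Depth matrix straight from vectors.
toy_dm <- function(pos, depth, groups = c("a", "a", "a", "b", "b", "b"),
                   chrom = "chr1", normalized = TRUE) {
  depth_matrix(rep(chrom, length(pos)), pos, depth, groups,
               normalized = normalized)
}

# Standard small simulated dataset used by several DMR tests: low
# dispersion so the mechanism (not the power at study conditions) is
# exercised.
sim_small <- function(seed = 7, n_dmrs = 5, effect = 3, dispersion = 0.02,
                      chrom_lengths = c(chr1 = 4e5, chr2 = 2e5)) {
  cfg <- sim_config(seed = seed, chrom_lengths = chrom_lengths,
                    n_dmrs = n_dmrs, dmr_effect = effect,
                    dispersion = dispersion)
  gm <- make_genome(cfg)
  truth <- plant_dmrs(gm, cfg)
  dm <- normalize_depths(filter_low_coverage(simulate_depths(gm, truth, cfg)))
  list(cfg = cfg, genome = gm, truth = truth, dm = dm)
}
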