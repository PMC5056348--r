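test_that("window profiles average member CpGs and report empty windows as missing", {
  gm <- toy_genome(c(chr1 = 300000L),
                   data.frame(chrom = "chr1",
                              pos = c(1000L, 5000L, 9000L, 150000L)))
  depth <- matrix(c(2, 4, 6, 8,
                    4, 8, 12, 16), ncol = 2,
                  dimnames = list(NULL, c("s1", "s2")))
  dm <- depth_matrix(gm$sites$chrom, gm$sites$pos, depth, c("a", "b"),
                     normalized = TRUE)
  wp <- window_profile(dm, gm, window_bp = 1e5)
  expect_identical(nrow(wp), 3L)
  # hand averages
  expect_equal(wp$mean_s1[1], mean(c(2, 4, 6)))
  expect_equal(wp$mean_s2[2], 16)
  # empty window is NA, not zero
  expect_true(is.na(wp$mean_s1[3]))
  expect_identical(wp$n_cpg, c(3L, 1L, 0L))

  # uniform depth -> every non-empty window mean equals it
  dmu <- depth_matrix(gm$sites$chrom, gm$sites$pos,
                      matrix(7, 4, 2, dimnames = list(NULL, c("s1", "s2"))),
                      c("a", "b"), normalized = TRUE)
  wpu <- window_profile(dmu, gm, window_bp = 1e5)
  expect_true(all(wpu$mean_s1[wpu$n_cpg > 0] == 7))

  # overlapping mode roughly doubles the window count
  wph <- window_profile(dm, gm, window_bp = 1e5, step_bp = 5e4)
  expect_gte(nrow(wph), 2L * nrow(wp) - 2L)
  expect_error(window_profile(dm, gm, window_bp = 0), "positive")

  # CpG input order does not matter
  shuf <- sample(4)
  dms <- depth_matrix(gm$sites$chrom[shuf], gm$sites$pos[shuf],
                      depth[shuf, ], c("a", "b"), normalized = TRUE)
  expect_equal(window_profile(dms, gm, window_bp = 1e5)$mean_s1, wp$mean_s1)
})

test_that("chromosome correlations reproduce the covariance formula", {
  # construct a profile whose per-window methylation is an exact linear
  # function of GC: r must be +-1
  mk_profile <- function(y, x, chroms) {
    data.frame(chrom = chroms, start = 0, end = 1000,
               n_cpg = 1L, gc = x, cpg_oe = x, mean_s1 = y,
               stringsAsFactors = FALSE)
  }
  x <- seq(0.3, 0.6, length.out = 10)
  wp <- mk_profile(2 * x + 1, x, "chr1")
  r <- chromosome_correlations(wp, mode = "window")
  expect_equal(r$r[r$feature == "gc"], 1, tolerance = 1e-12)
  wn <- mk_profile(-x, x, "chr1")
  expect_equal(chromosome_correlations(wn, mode = "window")$r[1], -1,
               tolerance = 1e-12)

  # formula oracle on random vectors
  set.seed(41)
  xr <- runif(10); yr <- rnorm(10)
  wr <- mk_profile(yr, xr, "chr1")
  got <- chromosome_correlations(wr, mode = "window")
  r_hand <- sum((xr - mean(xr)) * (yr - mean(yr))) /
    sqrt(sum((xr - mean(xr))^2) * sum((yr - mean(yr))^2))
  t_stat <- r_hand * sqrt(8 / (1 - r_hand^2))
  p_hand <- 2 * pt(abs(t_stat), df = 8, lower.tail = FALSE)
  expect_equal(got$r[got$feature == "gc"], r_hand, tolerance = 1e-12)
  expect_equal(got$p[got$feature == "gc"], p_hand, tolerance = 1e-12)

  # zero variance flagged
  wz <- mk_profile(rep(2, 10), xr, "chr1")
  expect_warning(expect_warning(chromosome_correlations(wz, mode = "window"),
                                "undefined"), "undefined")
  rz <- suppressWarnings(chromosome_correlations(wz, mode = "window"))
  expect_true(is.na(rz$r[1]))

  # chromosome mode needs >= 3 chromosomes and correlates one point each
  wc <- mk_profile(c(1, 1, 3, 3, 5, 5), rep(c(0.4, 0.5, 0.6), each = 2),
                   rep(c("chr1", "chr2", "chr3"), each = 2))
  wc$end <- rep(c(3e6, 2e6, 1e6), each = 2)
  rc <- chromosome_correlations(wc)
  expect_equal(rc$r[rc$feature == "length"], -1, tolerance = 1e-9)
  expect_equal(rc$r[rc$feature == "gc"], 1, tolerance = 1e-9)
  expect_error(chromosome_correlations(wc[wc$chrom != "chr3", ]), ">= 3")
})

test_that("gene metaprofiles are strand-aware and match hand binning", {
  # one + gene, uniform depth: flat profile
  sites <- data.frame(chrom = "chr1", pos = seq(2L, 19998L, by = 40L))
  dm <- depth_matrix(sites$chrom, sites$pos,
                     matrix(5, nrow(sites), 2,
                            dimnames = list(NULL, c("s1", "s2"))),
                     c("a", "b"), normalized = TRUE)
  gp <- gene_model(data.frame(gene_id = "g1", chrom = "chr1", start = 8000L,
                              end = 12000L, strand = "+"),
                   data.frame(gene_id = "g1", chrom = "chr1", start = 8000L,
                              end = 12000L))
  mp <- gene_metaprofile(dm, gp)
  expect_true(all(abs(mp$group_a[mp$n_cpg > 0] - 5) < 1e-12))
  expect_identical(nrow(mp), 80L)
  expect_identical(unique(mp$zone[1:20]), "upstream")
  expect_identical(unique(mp$zone[21:60]), "body")

  # a - strand gene on reflected depths mirrors the + strand profile
  L <- 20000L
  sites_m <- data.frame(chrom = "chr1", pos = L - 2L - rev(sites$pos))
  grad <- seq_len(nrow(sites))  # increasing depth along the chromosome
  dm_p <- depth_matrix(sites$chrom, sites$pos,
                       cbind(s1 = grad, s2 = grad), c("a", "b"),
                       normalized = TRUE)
  dm_m <- depth_matrix(sites_m$chrom, sites_m$pos,
                       cbind(s1 = rev(grad), s2 = rev(grad)), c("a", "b"),
                       normalized = TRUE)
  gm_m <- gene_model(data.frame(gene_id = "g1", chrom = "chr1",
                                start = L - 12000L, end = L - 8000L,
                                strand = "-"),
                     data.frame(gene_id = "g1", chrom = "chr1",
                                start = L - 12000L, end = L - 8000L))
  mp_p <- gene_metaprofile(dm_p, gp)
  mp_m <- gene_metaprofile(dm_m, gm_m)
  expect_equal(mp_m$group_a, mp_p$group_a, tolerance = 1e-9)

  # hand binning on a tiny case: flank 200 bp in 2 bins, body in 2 bins
  sites_h <- data.frame(chrom = "chr1",
                        pos = c(850L, 950L, 1200L, 1700L, 2050L))
  dm_h <- depth_matrix(sites_h$chrom, sites_h$pos,
                       cbind(s1 = c(1, 2, 3, 4, 5), s2 = c(1, 2, 3, 4, 5)),
                       c("a", "b"), normalized = TRUE)
  g_h <- gene_model(data.frame(gene_id = "g", chrom = "chr1", start = 1000L,
                               end = 2000L, strand = "+"),
                    data.frame(gene_id = "g", chrom = "chr1", start = 1000L,
                               end = 2000L))
  mp_h <- gene_metaprofile(dm_h, g_h, flank_bp = 200L, body_bins = 2L,
                           flank_bin_bp = 100L)
  expect_equal(mp_h$group_a, c(1, 2, 3, 4, 5, NA), tolerance = 1e-12)

  # genes shorter than the bin count are skipped with a warning
  g_s <- gene_model(data.frame(gene_id = "tiny", chrom = "chr1", start = 100L,
                               end = 120L, strand = "+"),
                    data.frame(gene_id = "tiny", chrom = "chr1", start = 100L,
                               end = 120L))
  expect_warning(gene_metaprofile(dm_h, g_s), "skipped")
})

test_that("sample clustering on DMR depths separates planted groups", {
  # 20-seed property at the generator's planted-DMR conditions (effect 3,
  # dispersion 0.2, site-level methylation heterogeneity): within-group
  # correlations exceed between-group ones in at least 90% of runs, and
  # the dendrogram's top split separates the groups
  run <- function(seed) {
    cfg <- sim_config(seed = seed, chrom_lengths = c(chr1 = 1.5e6, chr2 = 5e5),
                      n_dmrs = 50, dmr_effect = 3, dispersion = 0.2,
                      site_sd = 0.8)
    gm <- make_genome(cfg)
    truth <- plant_dmrs(gm, cfg)
    dm <- normalize_depths(filter_low_coverage(simulate_depths(gm, truth, cfg)))
    cl <- cluster_samples(dm, truth)
    grp <- dm$samples$group
    w <- cl$cor[outer(grp, grp, "==") & upper.tri(cl$cor)]
    b <- cl$cor[outer(grp, grp, "!=") & upper.tri(cl$cor)]
    top <- cutree(cl$hclust, k = 2)
    c(sep = min(w) > max(b),
      split = length(unique(top[grp == "g1"])) == 1 &&
        length(unique(top[grp == "g2"])) == 1)
  }
  res <- vapply(1:20, run, logical(2))
  expect_gte(mean(res["sep", ]), 0.9)
  expect_gte(mean(res["split", ]), 0.9)

  s <- sim_small(seed = 37, n_dmrs = 15, effect = 4, dispersion = 0.05,
                 chrom_lengths = c(chr1 = 5e5))
  cl <- cluster_samples(s$dm, s$truth)
  expect_true(isSymmetric(cl$cor))
  expect_equal(unname(diag(cl$cor)), rep(1, 6))

  # duplicated sample correlates at 1 and merges at height ~0
  dm2 <- depth_matrix(s$dm$chrom, s$dm$pos,
                      cbind(s$dm$depth, dup = s$dm$depth[, 1]),
                      c(s$dm$samples$group, "g2"), normalized = TRUE)
  cl2 <- cluster_samples(dm2, s$truth)
  expect_equal(cl2$cor[1, 7], 1, tolerance = 1e-12)
  expect_lt(cl2$hclust$height[1], 1e-12)

  # permuting sample order permutes the correlation matrix consistently
  perm <- c(4, 1, 5, 2, 6, 3)
  dmp <- depth_matrix(s$dm$chrom, s$dm$pos, s$dm$depth[, perm],
                      s$dm$samples$group[perm], normalized = TRUE)
  clp <- cluster_samples(dmp, s$truth)
  expect_equal(unname(clp$cor),
               unname(cl$cor[perm, perm]), tolerance = 1e-12)

  # constant sample vector errors
  dmc <- depth_matrix(s$dm$chrom, s$dm$pos,
                      cbind(s$dm$depth[, 1:5], flat = 3),
                      s$dm$samples$group, normalized = TRUE)
  expect_error(cluster_samples(dmc, s$truth), "constant")
})
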