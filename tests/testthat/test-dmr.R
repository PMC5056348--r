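test_that("the Bartlett gate matches the textbook formula and its conventions", {
  # equal spreads pass the gate
  expect_gt(bartlett_test(c(10, 11, 12), c(20, 21, 22)), 0.05)
  # wildly different spreads fail it
  p_het <- bartlett_test(c(10, 10.1, 9.9), c(5, 60, 200))
  expect_lt(p_het, 0.05)
  expect_equal(p_het, bartlett_hand(c(10, 10.1, 9.9), c(5, 60, 200)),
               tolerance = 1e-12)

  # location invariance
  x <- c(3, 9, 4); y <- c(1, 2, 8)
  expect_equal(bartlett_test(x, y), bartlett_test(x + 100, y + 100),
               tolerance = 1e-12)

  # agreement with stats::bartlett.test on random draws
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(3 + i %% 3, sd = runif(1, 0.5, 3))
    b <- rnorm(3 + (i + 1) %% 3, sd = runif(1, 0.5, 3))
    expect_equal(bartlett_test(a, b),
                 stats::bartlett.test(list(a, b))$p.value, tolerance = 1e-9)
  }

  # zero-variance conventions
  expect_message(p0 <- bartlett_test(c(5, 5, 5), c(7, 7, 7)), "zero variance")
  expect_identical(p0, 1)
  expect_identical(unname(bartlett_rows(matrix(c(5, 5, 5), 1),
                                        matrix(c(1, 9, 30), 1))), 0)
})

test_that("site tests match hand oracles; exact 3v3 Mann-Whitney bottoms out at 0.1", {
  expect_identical(site_test(c(4, 4, 4), c(4, 4, 4), "parametric"), 1)
  expect_identical(site_test(c(4, 4, 4), c(4, 4, 4), "nonparametric"), 1)

  p_t <- site_test(c(30, 31, 29), c(90, 88, 92), "parametric")
  expect_lt(p_t, 0.01)
  expect_equal(p_t, t_hand(c(30, 31, 29), c(90, 88, 92)), tolerance = 1e-12)
  expect_equal(p_t, t.test(c(30, 31, 29), c(90, 88, 92),
                           var.equal = TRUE)$p.value, tolerance = 1e-12)

  # the minimum attainable exact two-sided p at 3 vs 3, by full enumeration
  p_mw <- site_test(c(1, 2, 3), c(4, 5, 6), "nonparametric")
  expect_identical(p_mw, 0.1)
  expect_identical(mw_enum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(p_mw, wilcox.test(c(1, 2, 3), c(4, 5, 6),
                                 exact = TRUE)$p.value, tolerance = 1e-12)

  # enumeration agrees with wilcox.test on random tie-free data
  set.seed(2)
  for (i in 1:15) {
    n <- sample(3:5, 1)
    a <- sample(100, n); b <- sample(200:300, n)
    expect_equal(site_test(a, b, "nonparametric"),
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-9)
    expect_equal(site_test(a, b, "nonparametric"), mw_enum(a, b),
                 tolerance = 1e-12)
  }
  # and with ties, against the explicit enumeration oracle
  for (i in 1:10) {
    a <- sample(1:4, 3, replace = TRUE); b <- sample(2:5, 3, replace = TRUE)
    expect_equal(site_test(a, b, "nonparametric"), mw_enum(a, b),
                 tolerance = 1e-12)
  }

  # batch routing: route is parametric iff the gate passes
  dm <- toy_dm(seq(2L, by = 50L, length.out = 100),
               matrix(rpois(600, 30), ncol = 6), normalized = TRUE)
  st <- site_tests(dm)
  expect_identical(st$route == "parametric", st$bartlett_p > 0.05)
  expect_true(all(st$p >= 0 & st$p <= 1))
})

test_that("seed selection thresholds p-values in coordinate order", {
  prm <- dmr_params()
  expect_identical(find_seeds(data.frame(p = rep(0.5, 6)), prm), integer(0))
  expect_identical(find_seeds(data.frame(p = c(0.005, 0.02, 0.009)), prm),
                   c(1L, 3L))
  set.seed(3)
  p <- runif(500)
  expect_identical(find_seeds(data.frame(p = p), prm), which(p < 0.01))
})

test_that("seed extension equals brute-force maximal-run enumeration", {
  prm <- dmr_params()
  # five significant CpGs 50 bp apart, then a non-significant terminator
  pos <- c(seq(1000L, by = 50L, length.out = 5), 1400L, 5000L)
  p <- c(rep(0.001, 5), 0.5, 0.001)
  cand <- candidate_regions(rep("chr1", 7), pos, p, prm)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$start, 1000L)
  expect_identical(cand$end, 1200L + 2L)
  expect_identical(cand$n_sig, 5L)

  # four significant CpGs only: below the minimum
  p4 <- c(rep(0.001, 4), 0.5, 0.5, 0.5)
  expect_identical(nrow(candidate_regions(rep("chr1", 7), pos, p4, prm)), 0L)

  # a >200 bp gap splits an otherwise significant chain
  pos_gap <- c(seq(0L, by = 100L, length.out = 5),
               seq(900L, by = 100L, length.out = 5))
  p10 <- rep(0.001, 10)
  cand_gap <- candidate_regions(rep("chr1", 10), pos_gap, p10, prm)
  expect_identical(nrow(cand_gap), 2L)

  # randomized toy chains vs the brute-force enumerator
  set.seed(11)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    chrom <- sort(sample(c("chr1", "chr2"), n, replace = TRUE))
    pos_r <- unlist(lapply(split(seq_len(n), chrom), function(ix)
      cumsum(sample(c(10:250, 1500, 3000), length(ix), replace = TRUE))))
    p_r <- ifelse(runif(n) < 0.55, runif(n, 0, 0.0099), runif(n, 0.011, 1))
    got <- candidate_regions(chrom, pos_r, p_r, prm)
    want <- runs_brute(chrom, pos_r, p_r)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_sig, want$n_sig)
      # every seed inside a reported run extends to that same run
      for (r in seq_len(nrow(got))) {
        sig_members <- which(p_r < prm$seed_alpha &
                               seq_along(p_r) >= got$first[r] &
                               seq_along(p_r) <= got$last[r])
        for (sd_i in sig_members[c(1, length(sig_members))]) {
          ext <- extend_region(sd_i, chrom, pos_r, p_r, prm)
          expect_identical(ext$start, got$start[r])
          expect_identical(ext$end, got$end[r])
        }
      }
    }
  }
  expect_error(extend_region(1, "chr1", 100L, 0.5, prm), "not significant")
})

test_that("Benjamini-Hochberg equals the brute-force step-up", {
  expect_identical(benjamini_hochberg(0.037), 0.037)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4), tolerance = 1e-12)
  expect_equal(benjamini_hochberg(c(0.001, 0.004, 0.03, 0.5)),
               c(0.004, 0.008, 0.04, 0.5), tolerance = 1e-12)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0,1\\]")

  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    q <- benjamini_hochberg(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("permutation FDR ranks an overwhelming candidate at the minimum p", {
  s <- sim_small(seed = 13, n_dmrs = 3, effect = 6, dispersion = 0.005,
                 chrom_lengths = c(chr1 = 1.5e5))
  prm <- dmr_params(n_permutations = 200, seed = 13)
  res <- suppressWarnings(call_dmrs(s$dm, prm))
  expect_gt(nrow(res$candidates), 0)
  expect_identical(min(res$candidates$region_p), 1 / 201)
  expect_true(all(res$candidates$q >= res$candidates$region_p - 1e-12))
  # determinism of the permutation scheme
  res2 <- suppressWarnings(call_dmrs(s$dm, prm))
  expect_identical(res$candidates$region_p, res2$candidates$region_p)
  expect_error(dmr_params(n_permutations = 0), "n_permutations")
})

test_that("the caller recovers a planted region and is symmetric under label swap", {
  s <- sim_small(seed = 17, n_dmrs = 4, effect = 3, dispersion = 0.02,
                 chrom_lengths = c(chr1 = 3e5))
  prm <- dmr_params(n_permutations = 300, seed = 17)
  expect_warning(res <- call_dmrs(s$dm, prm), "nonparametric route starved")
  rec <- dmr_recovery(res, s$truth)
  expect_gt(rec$n_called, 0)
  expect_identical(rec$n_false, 0L)
  expect_identical(rec$direction_accuracy, 1)

  # group-label swap: directions flip, all else identical
  dm_sw <- depth_matrix(s$dm$chrom, s$dm$pos, s$dm$depth,
                        ifelse(s$dm$samples$group == "g1", "g2", "g1"),
                        lib_sizes = s$dm$lib_sizes, normalized = TRUE,
                        scale_factors = s$dm$scale_factors)
  res_sw <- suppressWarnings(call_dmrs(dm_sw, prm))
  expect_identical(res_sw$dmrs$start, res$dmrs$start)
  expect_identical(res_sw$dmrs$end, res$dmrs$end)
  expect_identical(res_sw$dmrs$region_p, res$dmrs$region_p)
  expect_identical(res_sw$dmrs$q, res$dmrs$q)
  expect_identical(res_sw$dmrs$direction,
                   ifelse(res$dmrs$direction == "hyper", "hypo", "hyper"))
  expect_identical(res_sw$sites$p, res$sites$p)

  # null matrix: nothing called
  sn <- sim_small(seed = 19, n_dmrs = 0, chrom_lengths = c(chr1 = 3e5))
  resn <- suppressWarnings(call_dmrs(sn$dm, dmr_params(n_permutations = 300,
                                                       seed = 19)))
  expect_identical(nrow(resn$dmrs), 0L)

  # too few samples per group
  dm_bad <- depth_matrix("chr1", 1L, matrix(1:3, 1), c("a", "a", "b"))
  expect_error(call_dmrs(dm_bad), "fewer than 2")

  # DMR output round-trips through BED/TSV
  pre <- file.path(tempdir(), "dmrs")
  write_dmrs(res, pre)
  back <- read_dmrs(paste0(pre, ".tsv"))
  expect_identical(nrow(back), nrow(res$dmrs))
  if (nrow(back) > 0) expect_equal(back$start, res$dmrs$start)
})
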