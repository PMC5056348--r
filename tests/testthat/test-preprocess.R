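phred_str <- function(qs) {
  vapply(qs, function(q) intToUtf8(33L + q), character(1))
}

make_read <- function(id, n_N = 0, n_lowq = 0, len = 50) {
  bases <- rep("A", len)
  if (n_N > 0) bases[seq_len(n_N)] <- "N"
  q <- rep(40L, len)
  if (n_lowq > 0) q[seq_len(n_lowq)] <- 4L
  data.frame(id = id, seq = paste(bases, collapse = ""),
             qual = intToUtf8(33L + q), stringsAsFactors = FALSE)
}

test_that("read QC applies the N and low-quality rules with strict boundaries", {
  reads <- rbind(
    make_read("six_N", n_N = 6),          # > 5 Ns -> dropped
    make_read("five_N", n_N = 5),         # exactly 5 -> kept
    make_read("lowq_26", n_lowq = 26),    # 52% below Phred 5 -> dropped
    make_read("lowq_25", n_lowq = 25),    # exactly 50% -> kept
    make_read("clean")
  )
  res <- qc_filter(reads)
  expect_setequal(res$reads$id, c("five_N", "lowq_25", "clean"))
  expect_identical(res$report$n_dropped_n, 1L)
  expect_identical(res$report$n_dropped_quality, 1L)
  expect_identical(res$report$n_input, 5L)
  expect_identical(res$report$n_kept, 3L)

  # Phred threshold boundary: a base at exactly Phred 5 is not low-quality
  q5 <- make_read("q5"); q5$qual <- intToUtf8(rep(33L + 5L, 50))
  expect_identical(qc_filter(q5)$report$n_dropped, 0L)

  # idempotence
  twice <- qc_filter(res$reads)
  expect_identical(twice$reads, res$reads)
  expect_identical(twice$report$n_dropped, 0L)

  # FASTQ round trip gives the same verdicts
  fq <- file.path(tempdir(), "qc.fastq")
  write_fastq(reads, fq)
  expect_setequal(qc_filter(fq)$reads$id, c("five_N", "lowq_25", "clean"))

  # malformed record is located
  fq_bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), fq_bad)  # qual length mismatch
  expect_error(read_fastq(fq_bad), "record 1")
})

test_that("duplicate collapsing keeps one coordinate-first record per read", {
  multi <- data.frame(
    id = "r1", chrom = c("chr2", "chr1", "chr1", "chr3"),
    start = c(500L, 900L, 100L, 7L), end = c(550L, 950L, 150L, 57L),
    strand = "+", n_hits = 4L, sample = "s1", stringsAsFactors = FALSE
  )
  out <- collapse_duplicates(multi)
  expect_identical(nrow(out), 1L)
  expect_identical(out$chrom, "chr1")
  expect_identical(out$start, 100L)
  expect_identical(out$n_hits, 4L)
  expect_identical(attr(out, "n_collapsed"), 1L)

  # all unique reads pass through unchanged
  uni <- data.frame(id = paste0("r", 1:5), chrom = "chr1",
                    start = c(10L, 30L, 20L, 50L, 40L),
                    end = c(20L, 40L, 30L, 60L, 50L), strand = "+",
                    n_hits = 1L, sample = "s1", stringsAsFactors = FALSE)
  outu <- collapse_duplicates(uni)
  expect_identical(nrow(outu), 5L)
  expect_identical(attr(outu, "n_collapsed"), 0L)
  expect_identical(outu$start, sort(uni$start))

  # counting: 1000 reads, 200 with a second alignment
  base <- data.frame(id = sprintf("r%04d", 1:1000), chrom = "chr1",
                     start = seq(0L, by = 10L, length.out = 1000),
                     end = seq(50L, by = 10L, length.out = 1000),
                     strand = "+", n_hits = 1L, sample = "s1",
                     stringsAsFactors = FALSE)
  base$n_hits[1:200] <- 2L
  dup <- base[1:200, ]
  dup$start <- dup$start + 100000L; dup$end <- dup$end + 100000L
  out2 <- collapse_duplicates(rbind(base, dup))
  expect_identical(nrow(out2), 1000L)
  expect_identical(attr(out2, "n_collapsed"), 200L)
})

test_that("CpG depth counting honors the half-open boundary convention", {
  groups <- c(s1 = "a", s2 = "b")
  reads <- data.frame(
    id = c("r1", "r2"), chrom = "chr1",
    start = c(100L, 100L), end = c(250L, 150L), strand = "+",
    n_hits = 1L, sample = c("s1", "s1"), stringsAsFactors = FALSE
  )
  sites <- data.frame(chrom = "chr1", pos = c(149L, 150L, 400L))
  dm <- suppressWarnings(cpg_depth(reads, sites, groups))
  # fragment [100,250) covers both sites; [100,150) covers 149 (base 149 of
  # the dinucleotide 149-150) but not 150
  expect_identical(unname(dm$depth[, "s1"]), c(2L, 1L, 0L))
  expect_identical(unname(dm$depth[, "s2"]), c(0L, 0L, 0L))

  # unknown chromosome warns and yields zero depth
  sites2 <- data.frame(chrom = c("chr1", "chrZ"), pos = c(149L, 10L))
  expect_warning(dm2 <- cpg_depth(reads, sites2, groups), "chrZ")
  expect_identical(unname(dm2$depth[dm2$chrom == "chrZ", "s1"]), 0L)

  # random fragments match the brute-force overlap count
  set.seed(42)
  n <- 2000
  rr <- data.frame(
    id = sprintf("r%05d", 1:n),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample.int(49000, n, replace = TRUE),
    strand = "+", n_hits = 1L,
    sample = sample(c("s1", "s2"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  rr$end <- rr$start + sample(30:300, n, replace = TRUE)
  ss <- data.frame(chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
                   pos = sample.int(50000, 300))
  ss <- ss[order(ss$chrom, ss$pos), ]
  dm3 <- cpg_depth(rr, ss, groups)
  expect_identical(unname(dm3$depth), unname(overlap_brute(rr, ss)))
})

test_that("coverage filtering uses group-mean depth with an inclusive threshold", {
  depth <- rbind(
    c(9, 10, 10.7, 30, 30, 30),   # group-1 mean 9.9 -> removed
    c(10, 10, 10, 10, 10, 10),    # exactly 10 -> kept
    c(40, 40, 40, 9, 9, 9)        # group-2 mean below -> removed
  )
  dm <- toy_dm(c(100L, 200L, 300L), depth, normalized = FALSE)
  kept <- filter_low_coverage(dm, 10)
  expect_identical(kept$pos, 200L)

  # per-sample mode is stricter
  depth2 <- rbind(c(9, 11, 10, 12, 12, 12), c(10, 10, 10, 10, 10, 10))
  dm2 <- toy_dm(c(10L, 20L), depth2, normalized = FALSE)
  expect_identical(filter_low_coverage(dm2, 10)$pos, c(10L, 20L))
  expect_identical(filter_low_coverage(dm2, 10, mode = "per-sample")$pos, 20L)

  expect_error(filter_low_coverage(dm, 0), "min_depth")

  # oracle recount on random data
  set.seed(7)
  d <- matrix(rpois(600 * 6, 12), ncol = 6)
  dm3 <- toy_dm(seq(2L, by = 5L, length.out = 600), d, normalized = FALSE)
  keep <- rowMeans(d[, 1:3]) >= 10 & rowMeans(d[, 4:6]) >= 10
  expect_identical(filter_low_coverage(dm3, 10)$pos, dm3$pos[keep])
})

test_that("normalization equalizes library sizes within groups and preserves ratios", {
  depth <- matrix(rpois(5 * 30, 20), ncol = 5)
  dm <- depth_matrix(rep("chr1", 30), seq(2L, by = 10L, length.out = 30),
                     depth, groups = c("a", "a", "a", "b", "b"),
                     lib_sizes = c(100, 200, 300, 50, 50))
  nm <- normalize_depths(dm)
  expect_equal(unname(nm$scale_factors), c(2, 1, 2 / 3, 1, 1))
  expect_equal(unname(nm$depth[, 1]), 2 * unname(depth[, 1]))
  # within-sample ratios preserved exactly
  nz <- depth[, 3] > 0
  expect_equal(nm$depth[nz, 3] / depth[nz, 3],
               rep(2 / 3, sum(nz)), tolerance = 1e-12)

  # equal libraries -> identity
  dme <- depth_matrix(rep("chr1", 30), seq(2L, by = 10L, length.out = 30),
                      depth, groups = c("a", "a", "a", "b", "b"),
                      lib_sizes = rep(120, 5))
  expect_equal(unname(normalize_depths(dme)$depth), unname(depth))

  # doubling one sample's depths (library size tracking column sums):
  # rescaling a sample is absorbed up to the common within-group factor
  # that its new library size contributes to the group mean
  dmc <- toy_dm(seq(2L, by = 10L, length.out = 30), depth,
                groups = c("a", "a", "a", "b", "b"), normalized = FALSE)
  d2 <- depth; d2[, 2] <- 2 * d2[, 2]
  dmc2 <- toy_dm(seq(2L, by = 10L, length.out = 30), d2,
                 groups = c("a", "a", "a", "b", "b"), normalized = FALSE)
  n1 <- normalize_depths(dmc)$depth; n2 <- normalize_depths(dmc2)$depth
  ratio <- n2[, 1:3] / n1[, 1:3]
  expect_equal(as.numeric(ratio[is.finite(ratio)]),
               rep(as.numeric(ratio[1, 1]), sum(is.finite(ratio))),
               tolerance = 1e-12)
  expect_equal(n2[, 4:5], n1[, 4:5], tolerance = 1e-12)

  expect_error(normalize_depths(
    depth_matrix("chr1", 1L, matrix(0, 1, 4), c("a", "a", "b", "b"))),
    "zero library")
})

test_that("SAM ingestion matches BED ingestion and honors the NH tag", {
  sam <- file.path(tempdir(), "toy.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr1\tLN:10000",
    # POS is 1-based: 101 -> 0-based start 100, 50M -> end 150
    "r1\t0\tchr1\t101\t60\t50M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*\tNH:i:1",
    "r2\t16\tchr1\t201\t60\t50M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*\tNH:i:3",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\t*"  # unmapped: excluded
  ), sam)
  aln <- read_aligned_sam(sam, sample = "s1")
  expect_identical(nrow(aln), 2L)
  expect_identical(aln$start, c(100L, 200L))
  expect_identical(aln$end, c(150L, 250L))
  expect_identical(aln$n_hits, c(1L, 3L))
  expect_identical(aln$strand, c("+", "-"))

  bed <- file.path(tempdir(), "toy.bed")
  write.table(data.frame("chr1", c(100L, 200L), c(150L, 250L),
                         c("r1/1", "r2/3"), c(1L, 3L), c("+", "-")),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  aln_bed <- read_aligned_bed(bed, sample = "s1")
  expect_identical(aln_bed[, c("id", "chrom", "start", "end", "n_hits")],
                   aln[, c("id", "chrom", "start", "end", "n_hits")])
})
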