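# Genome-scale methylome description: window tracks, chromosome
# correlations, gene-body metaprofiles, sample clustering.

#' Sliding-window methylation profile
#'
#' Windows tile each chromosome (default 1 Mb, non-overlapping; pass
#' `step_bp < window_bp` for overlapping smoothing).  Each window reports
#' the mean normalized depth of its member CpGs per sample and per group;
#' windows without CpGs report NA, not zero.  Window GC and CpG_o/e are
#' overlap-length-weighted means of the genome model's track windows.
#'
#' @param dm A normalized [depth_matrix()].
#' @param genome The `genome_model` (chromosome lengths + GC/CpG_o/e track).
#' @param window_bp Window size (> 0).
#' @param step_bp Step between window starts (default = `window_bp`).
#' @return data.frame of class `window_profile`: chrom, start, end, n_cpg,
#'   gc, cpg_oe, one `mean_<sample>` column per sample and
#'   `group_<label>` per group.
#' @export
window_profile <- function(dm, genome, window_bp = 1e6, step_bp = window_bp) {
  if (window_bp <= 0) stop("window_bp must be positive")
  if (step_bp <= 0) stop("step_bp must be positive")
  lens <- genome$chrom_lengths
  wins <- do.call(rbind, lapply(names(lens), function(ch) {
    starts <- seq.int(0L, max(0L, as.integer(lens[ch]) - 1L), by = step_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_bp, as.integer(lens[ch])),
               stringsAsFactors = FALSE)
  }))
  w_gr <- GenomicRanges::GRanges(wins$chrom,
                                 IRanges::IRanges(wins$start + 1L, wins$end))
  s_gr <- depth_granges(dm)
  hits <- GenomicRanges::findOverlaps(w_gr, s_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  n_win <- nrow(wins); n_smp <- ncol(dm$depth)
  means <- matrix(NA_real_, n_win, n_smp,
                  dimnames = list(NULL, paste0("mean_", dm$samples$sample)))
  n_cpg <- integer(n_win)
  if (length(qh)) {
    cnt <- tabulate(qh, n_win)
    n_cpg <- cnt
    for (j in seq_len(n_smp)) {
      s <- rowsum(dm$depth[sh, j], qh)
      means[as.integer(rownames(s)), j] <- s[, 1] / cnt[as.integer(rownames(s))]
    }
  }
  # track annotation: overlap-weighted GC / CpG_o/e
  t_gr <- GenomicRanges::GRanges(
    genome$windows$chrom,
    IRanges::IRanges(genome$windows$start + 1L, genome$windows$end))
  th <- GenomicRanges::findOverlaps(w_gr, t_gr)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(w_gr)[S4Vectors::queryHits(th)],
    IRanges::ranges(t_gr)[S4Vectors::subjectHits(th)]))
  wq <- S4Vectors::queryHits(th); ws <- S4Vectors::subjectHits(th)
  gc <- oe <- rep(NA_real_, n_win)
  if (length(wq)) {
    den <- rowsum(ov, wq)
    gnum <- rowsum(ov * genome$windows$gc[ws], wq)
    onum <- rowsum(ov * genome$windows$cpg_oe[ws], wq)
    rows <- as.integer(rownames(den))
    gc[rows] <- gnum[, 1] / den[, 1]
    oe[rows] <- onum[, 1] / den[, 1]
  }
  out <- data.frame(wins, n_cpg = n_cpg, gc = gc, cpg_oe = oe,
                    means, check.names = FALSE)
  gcols <- group_columns(dm)
  out[[paste0("group_", gcols$labels[1])]] <-
    rowMeans(means[, gcols$g1, drop = FALSE])
  out[[paste0("group_", gcols$labels[2])]] <-
    rowMeans(means[, gcols$g2, drop = FALSE])
  class(out) <- c("window_profile", "data.frame")
  out
}

# Pearson r with two-sided p from the t transform; zero variance -> NA + flag
.pearson <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || var(x) == 0 || var(y) == 0) {
    warning("correlation undefined (fewer than 3 points or zero variance)")
    return(c(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Chromosome-level correlations of methylation with genomic features
#'
#' Aggregates a [window_profile()] to one point per chromosome (mean of
#' window means across all samples; `mode = "window"` instead correlates
#' across windows) and reports Pearson r and two-sided p of methylation
#' against chromosome length, GC content and CpG_o/e.
#'
#' @param profile A `window_profile`.
#' @param mode `"chromosome"` (default) or `"window"`.
#' @return data.frame with rows `length`, `gc`, `cpg_oe` and columns
#'   r, p, n.  (`length` is dropped in window mode.)
#' @export
chromosome_correlations <- function(profile, mode = c("chromosome", "window")) {
  mode <- match.arg(mode)
  smp_cols <- grep("^mean_", names(profile), value = TRUE)
  if (length(smp_cols) == 0)
    smp_cols <- setdiff(names(profile),
                        c("chrom", "start", "end", "n_cpg", "gc", "cpg_oe"))
  meth <- rowMeans(profile[, smp_cols, drop = FALSE])
  if (mode == "chromosome") {
    chroms <- unique(profile$chrom)
    if (length(chroms) < 3)
      stop("chromosome-level correlation needs >= 3 chromosomes")
    agg <- function(v) vapply(chroms, function(ch)
      mean(v[profile$chrom == ch], na.rm = TRUE), numeric(1))
    m <- agg(meth)
    len <- vapply(chroms, function(ch)
      max(profile$end[profile$chrom == ch]), numeric(1))
    res <- rbind(length = .pearson(m, len),
                 gc = .pearson(m, agg(profile$gc)),
                 cpg_oe = .pearson(m, agg(profile$cpg_oe)))
  } else {
    res <- rbind(gc = .pearson(meth, profile$gc),
                 cpg_oe = .pearson(meth, profile$cpg_oe))
  }
  data.frame(feature = rownames(res), res, row.names = NULL)
}

#' Gene-body metaprofile
#'
#' Averages normalized depth over genes in a strand-aware frame running
#' from `flank_bp` upstream of the TSS, across the gene body rescaled to
#' `body_bins` bins, to `flank_bp` downstream of the TES.  Flanks use
#' fixed-width bins of `flank_bin_bp`.  Genes shorter than `body_bins` bp
#' are skipped with a warning.
#'
#' @param dm A normalized [depth_matrix()].
#' @param gm A [gene_model()].
#' @param flank_bp Flank length (default 2000).
#' @param body_bins Gene-body bin count (default 40).
#' @param flank_bin_bp Flank bin width (default 100).
#' @return data.frame with bin index, zone (upstream/body/downstream),
#'   oriented bin midpoint offset, and mean depth per group.
#' @export
gene_metaprofile <- function(dm, gm, flank_bp = 2000L, body_bins = 40L,
                             flank_bin_bp = 100L) {
  g <- gm$genes
  short <- (g$end - g$start) < body_bins
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than ", body_bins, " bp skipped")
    g <- g[!short, , drop = FALSE]
  }
  n_flank <- as.integer(flank_bp / flank_bin_bp)
  n_bins <- 2L * n_flank + body_bins
  gcols <- group_columns(dm)
  acc1 <- acc2 <- numeric(n_bins)
  cnt <- integer(n_bins)
  ext_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(0L, g$start - flank_bp) + 1L,
                              g$end + flank_bp))
  s_gr <- depth_granges(dm)
  hits <- GenomicRanges::findOverlaps(ext_gr, s_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    pos <- dm$pos[sh]
    gs <- g$start[qh]; ge <- g$end[qh]
    len <- ge - gs
    u <- ifelse(g$strand[qh] == "+", pos - gs, (ge - 1L) - pos)  # oriented
    zone_up <- u < 0 & u >= -flank_bp
    zone_body <- u >= 0 & u < len
    zone_dn <- u >= len & u < len + flank_bp
    bin <- rep(NA_integer_, length(u))
    bin[zone_up] <- 1L + floor((u[zone_up] + flank_bp) / flank_bin_bp)
    bin[zone_body] <- n_flank + 1L +
      floor(u[zone_body] / len[zone_body] * body_bins)
    bin[zone_dn] <- n_flank + body_bins + 1L +
      floor((u[zone_dn] - len[zone_dn]) / flank_bin_bp)
    ok <- !is.na(bin) & bin >= 1L & bin <= n_bins
    d1 <- rowMeans(dm$depth[sh, gcols$g1, drop = FALSE])
    d2 <- rowMeans(dm$depth[sh, gcols$g2, drop = FALSE])
    acc1 <- rowsum(d1[ok], bin[ok])
    acc2 <- rowsum(d2[ok], bin[ok])
    cnt_t <- tabulate(bin[ok], n_bins)
    m1 <- m2 <- rep(NA_real_, n_bins)
    rows <- as.integer(rownames(acc1))
    m1[rows] <- acc1[, 1] / cnt_t[rows]
    m2[rows] <- acc2[, 1] / cnt_t[rows]
    cnt <- cnt_t
  } else m1 <- m2 <- rep(NA_real_, n_bins)
  zone <- c(rep("upstream", n_flank), rep("body", body_bins),
            rep("downstream", n_flank))
  out <- data.frame(bin = seq_len(n_bins), zone = zone, n_cpg = cnt,
                    stringsAsFactors = FALSE)
  out[[paste0("group_", gcols$labels[1])]] <- m1
  out[[paste0("group_", gcols$labels[2])]] <- m2
  out
}

#' Hierarchical clustering of samples on DMR depths
#'
#' Restricts the depth matrix to CpGs inside the given regions, computes
#' the pairwise Pearson correlation of samples, and clusters with average
#' linkage on distance 1 - r.
#'
#' @param dm A normalized [depth_matrix()].
#' @param regions data.frame of regions (chrom, start, end; e.g. called
#'   DMRs or a planted truth set).
#' @return A `cluster_result`: list with `cor` (sample correlation matrix)
#'   and `hclust` (the dendrogram).
#' @export
cluster_samples <- function(dm, regions) {
  if (ncol(dm$depth) < 2) stop("need >= 2 samples")
  if (nrow(regions) < 2) stop("need >= 2 regions")
  r_gr <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L, regions$end))
  keep <- GenomicRanges::countOverlaps(depth_granges(dm), r_gr) > 0
  if (sum(keep) < 2) stop("fewer than 2 CpGs fall inside the regions")
  x <- dm$depth[keep, , drop = FALSE]
  if (any(apply(x, 2, var) == 0))
    stop("constant sample vector: correlation undefined")
  R <- cor(x)
  hc <- hclust(as.dist(1 - R), method = "average")
  structure(list(cor = R, hclust = hc), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", ncol(x$cor), "samples; mean off-diagonal r =",
      round(mean(x$cor[lower.tri(x$cor)]), 3), "\n")
  invisible(x)
}
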