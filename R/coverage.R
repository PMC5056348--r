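#' Count fragment depth at each CpG site
#'
#' Depth of a site for a sample is the number of that sample's fragments
#' whose 0-based half-open interval `[start, end)` overlaps the 2-bp
#' dinucleotide `[pos, pos+2)`; both strands count toward the same
#' (strand-symmetric) site.  Overlap counting is done with
#' [GenomicRanges::countOverlaps()].
#'
#' @param reads Collapsed aligned-read data.frame (one record per read;
#'   see [collapse_duplicates()]) with a `sample` column.
#' @param cpg_sites data.frame with `chrom` and `pos` (0-based C position),
#'   or a `genome_model`.
#' @param groups Named character vector mapping sample id to group label.
#' @return A raw [depth_matrix()]; library sizes are the per-sample
#'   post-collapse fragment counts.
#' @export
cpg_depth <- function(reads, cpg_sites, groups) {
  if (inherits(cpg_sites, "genome_model")) cpg_sites <- cpg_sites$sites
  ord <- order(cpg_sites$chrom, cpg_sites$pos)
  cpg_sites <- cpg_sites[ord, , drop = FALSE]
  samples <- names(groups)
  if (is.null(samples)) stop("groups must be a named vector (sample -> group)")
  unknown <- setdiff(unique(cpg_sites$chrom), unique(reads$chrom))
  if (length(unknown))
    warning("CpG sites on chromosomes absent from the reads (zero depth): ",
            paste(unknown, collapse = ", "))
  site_gr <- GenomicRanges::GRanges(
    cpg_sites$chrom, IRanges::IRanges(start = cpg_sites$pos + 1L, width = 2L))
  depth <- matrix(0L, nrow = nrow(cpg_sites), ncol = length(samples),
                  dimnames = list(NULL, samples))
  libs <- setNames(numeric(length(samples)), samples)
  for (s in samples) {
    r <- reads[reads$sample == s, , drop = FALSE]
    libs[s] <- nrow(r)
    if (nrow(r) == 0) next
    read_gr <- GenomicRanges::GRanges(
      r$chrom, IRanges::IRanges(start = r$start + 1L, end = r$end))
    depth[, s] <- GenomicRanges::countOverlaps(site_gr, read_gr)
  }
  depth_matrix(cpg_sites$chrom, cpg_sites$pos, depth,
               groups = unname(groups[samples]), lib_sizes = libs)
}

#' Filter CpG sites by read-depth coverage
#'
#' Removes low-coverage sites before testing, guarding against stochastic
#' sampling drift.  Default mode retains a site iff its per-group MEAN raw
#' depth is at least `min_depth` in BOTH groups; `mode = "per-sample"`
#' instead requires every single sample to reach `min_depth`.
#'
#' @param dm A raw (unnormalized) [depth_matrix()].
#' @param min_depth Depth threshold (default 10; sites below it are
#'   removed, sites exactly at it kept).
#' @param mode `"group-mean"` (default) or `"per-sample"`.
#' @return The filtered `depth_matrix` (site order preserved).
#' @export
filter_low_coverage <- function(dm, min_depth = 10,
                                mode = c("group-mean", "per-sample")) {
  mode <- match.arg(mode)
  if (min_depth < 1) stop("min_depth must be >= 1")
  if (dm$normalized)
    warning("coverage filter applied to a normalized matrix; ",
            "the depth threshold is defined on raw counts")
  gc <- group_columns(dm)
  keep <- if (mode == "group-mean") {
    rowMeans(dm$depth[, gc$g1, drop = FALSE]) >= min_depth &
      rowMeans(dm$depth[, gc$g2, drop = FALSE]) >= min_depth
  } else {
    apply(dm$depth, 1, min) >= min_depth
  }
  subset_sites(dm, keep)
}

#' Normalize depths to each group's mean library size
#'
#' Sample `s` in group `g` is rescaled by
#' `factor_s = mean(lib sizes of g) / lib_size_s`, so every sample's
#' effective library size becomes its group's pre-normalization average and
#' within-sample depth ratios are preserved exactly.
#'
#' @param dm A raw [depth_matrix()] with library sizes (defaulting to
#'   column sums when not recorded from alignment counts).
#' @return The normalized `depth_matrix` (`normalized = TRUE`,
#'   `scale_factors` filled in).
#' @export
normalize_depths <- function(dm) {
  if (dm$normalized) return(dm)
  if (any(dm$lib_sizes <= 0)) stop("zero library size; cannot normalize")
  gc <- group_columns(dm)
  fac <- numeric(ncol(dm$depth))
  for (g in list(gc$g1, gc$g2)) fac[g] <- mean(dm$lib_sizes[g]) / dm$lib_sizes[g]
  depth <- sweep(dm$depth, 2, fac, "*")
  depth_matrix(dm$chrom, dm$pos, depth, dm$samples$group,
               lib_sizes = dm$lib_sizes, normalized = TRUE,
               scale_factors = fac)
}
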