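#' Expected CpG count of a window
#'
#' Closed-form expectation used by the genome generator: with GC fraction
#' `gc` and observed/expected CpG ratio `oe`, the expected number of CpG
#' dinucleotides in `width` bp is `width * oe * (gc/2)^2` (each of C and G
#' occurs at frequency gc/2 under the window's base composition).
#'
#' @param width Window width in bp.
#' @param gc GC fraction in \[0,1\].
#' @param oe Observed/expected CpG ratio (>= 0).
#' @return Expected CpG dinucleotide count (numeric).
#' @export
expected_cpg_count <- function(width, gc, oe) {
  width * oe * (gc / 2)^2
}

#' Generate a synthetic genome model
#'
#' Builds a small multi-chromosome genome: per-window GC and CpG_o/e tracks
#' and CpG site coordinates whose density follows the closed-form link of
#' [expected_cpg_count()], so CpG density increases monotonically with
#' window GC at fixed CpG_o/e.  Shorter chromosomes get a higher baseline
#' GC, mirroring the GC/length anticorrelation of mammalian genomes.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `genome_model`: list with `chrom_lengths` (named vector),
#'   `windows` (data.frame chrom/start/end/gc/cpg_oe/n_cpg) and `sites`
#'   (data.frame chrom/pos, 0-based position of the C, strictly increasing
#'   within each chromosome).
#' @export
make_genome <- function(config) {
  validate_sim_config(config)
  lens <- config$chrom_lengths
  with_seed(config$seed, {
    # GC baseline: longest chromosome at gc_range[1], shortest at gc_range[2]
    r <- rank(-lens, ties.method = "first")
    frac <- if (length(lens) == 1L) 0.5 else (r - 1) / (length(lens) - 1)
    gc_base <- config$gc_range[1] + frac * diff(config$gc_range)

    win_list <- vector("list", length(lens))
    site_list <- vector("list", length(lens))
    for (i in seq_along(lens)) {
      len <- as.integer(lens[i])
      starts <- seq.int(0L, len - 1L, by = config$window_bp)
      ends <- pmin(starts + config$window_bp, len)
      gc <- pmin(1, pmax(0, gc_base[i] + rnorm(length(starts), 0, config$gc_jitter_sd)))
      oe <- pmax(0, config$cpg_oe + rnorm(length(starts), 0, config$cpg_oe_sd))
      lambda <- expected_cpg_count(ends - starts, gc, oe)
      n <- rpois(length(lambda), lambda)
      pos <- vector("list", length(starts))
      for (w in seq_along(starts)) {
        avail <- ends[w] - starts[w] - 1L  # C must sit at pos <= end-2
        nw <- min(n[w], max(avail, 0L))
        n[w] <- nw
        if (nw > 0L)
          pos[[w]] <- starts[w] + sort(sample.int(avail, nw)) - 1L
      }
      win_df <- data.frame(
        chrom = names(lens)[i], start = starts, end = ends,
        gc = gc, cpg_oe = oe, n_cpg = n, stringsAsFactors = FALSE
      )
      p <- unlist(pos, use.names = FALSE)
      if (!is.null(p) && length(p) > 1) {
        # forward-strand CpG dinucleotides cannot overlap: spacing >= 2
        keep <- rep(TRUE, length(p))
        last <- p[1]
        for (s in seq_along(p)[-1]) {
          if (p[s] - last < 2L) keep[s] <- FALSE else last <- p[s]
        }
        p <- p[keep]
      }
      if (is.null(p)) p <- integer(0)
      win_df$n_cpg <- tabulate(findInterval(p, starts), length(starts))
      win_list[[i]] <- win_df
      site_list[[i]] <- data.frame(
        chrom = rep(names(lens)[i], length(p)),
        pos = p, stringsAsFactors = FALSE
      )
    }
    gm <- list(
      chrom_lengths = lens,
      windows = do.call(rbind, win_list),
      sites = do.call(rbind, site_list)
    )
    rownames(gm$windows) <- rownames(gm$sites) <- NULL
    class(gm) <- "genome_model"
    gm
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_lengths), "chromosomes,",
      sum(as.numeric(x$chrom_lengths)), "bp,", nrow(x$sites), "CpG sites\n")
  invisible(x)
}

#' CpG sites of a genome model as GRanges
#'
#' @param genome A `genome_model`.
#' @return A [GenomicRanges::GRanges] of width-2 CpG dinucleotide intervals
#'   (1-based internally, matching the 0-based half-open `[pos, pos+2)`).
#' @export
cpg_granges <- function(genome) {
  GenomicRanges::GRanges(
    genome$sites$chrom,
    IRanges::IRanges(start = genome$sites$pos + 1L, width = 2L),
    seqlengths = genome$chrom_lengths
  )
}

#' Write / read a genome model as plain-text files
#'
#' Writes `chrom.sizes` (chrom, length), `cpg_sites.bed` (BED3 of the CpG
#' dinucleotides) and `windows.tsv` (GC / CpG_o/e track) into `dir`.
#'
#' @param genome A `genome_model`.
#' @param dir Output directory (created if needed).
#' @return `write_genome()` returns `dir` invisibly; `read_genome()` returns
#'   a `genome_model`.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(
    data.frame(names(genome$chrom_lengths), as.integer(genome$chrom_lengths)),
    file.path(dir, "chrom.sizes"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  write.table(
    data.frame(genome$sites$chrom, genome$sites$pos, genome$sites$pos + 2L),
    file.path(dir, "cpg_sites.bed"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  write.table(genome$windows, file.path(dir, "windows.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_genome
#' @export
read_genome <- function(dir) {
  cs <- read.delim(file.path(dir, "chrom.sizes"), header = FALSE,
                   col.names = c("chrom", "length"))
  bed <- read.delim(file.path(dir, "cpg_sites.bed"), header = FALSE,
                    col.names = c("chrom", "start", "end"))
  gm <- list(
    chrom_lengths = setNames(as.integer(cs$length), cs$chrom),
    windows = read.delim(file.path(dir, "windows.tsv")),
    sites = data.frame(chrom = bed$chrom, pos = bed$start,
                       stringsAsFactors = FALSE)
  )
  class(gm) <- "genome_model"
  gm
}

#' Read CpG site coordinates from a BED3 file
#'
#' @param path BED3 file of CpG dinucleotide intervals (0-based half-open).
#' @return data.frame with `chrom` and `pos` (0-based position of the C).
#' @export
read_cpg_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1L,
    stringsAsFactors = FALSE
  )
}
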