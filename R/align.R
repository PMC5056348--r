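#' Read aligned fragments from a BED6 file
#'
#' Coordinates stay 0-based half-open.  The hit count is parsed from the
#' name field (`<id>/<n_hits>`, the layout written by [write_reads_bed()]);
#' names without the suffix get `n_hits = 1`.
#'
#' @param path BED6 file.
#' @param sample Sample id to attach to every record.
#' @return data.frame with id, chrom, start, end, strand, n_hits, sample.
#' @export
read_aligned_bed <- function(path, sample) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- if (!is.null(gr$name)) gr$name else
    sprintf("%s_r%06d", sample, seq_along(gr))
  has_nh <- grepl("/[0-9]+$", nm)
  n_hits <- rep(1L, length(nm))
  n_hits[has_nh] <- as.integer(sub("^.*/", "", nm[has_nh]))
  id <- sub("/[0-9]+$", "", nm)
  data.frame(
    id = id,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    n_hits = n_hits,
    sample = sample,
    stringsAsFactors = FALSE
  )
}

#' Read aligned reads from a SAM file
#'
#' Mapped, non-secondary records only; the NH tag supplies the hit count
#' when present.  The SAM text is converted to a temporary BAM with
#' [Rsamtools::asBam()] before parsing.
#'
#' @param path SAM file.
#' @param sample Sample id to attach.
#' @return Same layout as [read_aligned_bed()].
#' @export
read_aligned_sam <- function(path, sample) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE),
    what = "qname", tag = "NH"
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  nh <- S4Vectors::mcols(ga)$NH
  if (is.null(nh)) nh <- rep(1L, length(ga))
  nh[is.na(nh)] <- 1L
  data.frame(
    id = S4Vectors::mcols(ga)$qname,
    chrom = as.character(GenomeInfoDb::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    n_hits = as.integer(nh),
    sample = sample,
    stringsAsFactors = FALSE
  )
}

#' Collapse multi-location alignments to one record per read
#'
#' A read aligned to several genomic locations is treated as a duplicate
#' and kept as a single record: the first alignment in (chrom, start, end)
#' order.  `n_hits` is preserved on the surviving record for reporting.
#'
#' @param reads Aligned-read data.frame (id, chrom, start, end, strand,
#'   n_hits, sample).
#' @return The collapsed data.frame, with attribute `n_collapsed` giving
#'   the number of reads that had more than one alignment record.
#' @export
collapse_duplicates <- function(reads) {
  ord <- order(reads$sample, reads$id, reads$chrom, reads$start, reads$end)
  r <- reads[ord, , drop = FALSE]
  key <- paste0(r$sample, "\r", r$id)
  first <- !duplicated(key)
  out <- r[first, , drop = FALSE]
  out <- out[order(out$sample, out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_collapsed") <- length(unique(key[!first]))
  out
}

#' Restrict aligned reads to QC-passing fragments
#'
#' @param reads Aligned-read data.frame.
#' @param keep_ids Read ids that passed [qc_filter()].
#' @return The subset of `reads` with `id` in `keep_ids`.
#' @export
filter_aligned_by_qc <- function(reads, keep_ids) {
  out <- reads[reads$id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}
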