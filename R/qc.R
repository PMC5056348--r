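#' Read a FASTQ file
#'
#' Thin wrapper over [Biostrings::readQualityScaledDNAStringSet()] returning
#' a plain data.frame.  Records must use the standard 4-line layout;
#' malformed files are reported with the index of the offending record.
#'
#' @param path FASTQ file path (Phred+33 qualities).
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # structural validation first: Biostrings is not defined on records whose
  # quality line length disagrees with the sequence line
  lines <- readLines(path, warn = FALSE)
  n_rec <- length(lines) %/% 4L
  for (i in seq_len(n_rec)) {
    b <- lines[(i - 1L) * 4L + 1:4]
    if (!startsWith(b[1], "@") || !startsWith(b[3], "+") ||
        nchar(b[2]) != nchar(b[4]))
      stop("malformed FASTQ record at record ", i, call. = FALSE)
  }
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ record at record ", n_rec + 1L,
         " (truncated file)", call. = FALSE)
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  data.frame(id = sub(" .*$", "", names(x)), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Quality-filter sequencing reads
#'
#' A read is discarded iff it contains more than `max_n` 'N' bases OR more
#' than `max_lowq_frac` of its bases fall below Phred `min_phred` (both
#' comparisons strict, offset-33 encoding).  The defaults reproduce the
#' standard MeDIP-seq pre-alignment filter: >5 Ns, or Phred < 5 on >50% of
#' the sequence.
#'
#' @param reads data.frame with `id`, `seq`, `qual` (e.g. from
#'   [read_fastq()]), or a FASTQ path.
#' @param max_n Maximum tolerated 'N' count.
#' @param min_phred Phred threshold defining a low-quality base.
#' @param max_lowq_frac Maximum tolerated fraction of low-quality bases.
#' @return List with `reads` (the passing records) and `report` (named list:
#'   `n_input`, `n_kept`, `n_dropped`, `n_dropped_n`, `n_dropped_quality`).
#' @export
qc_filter <- function(reads, max_n = 5L, min_phred = 5L, max_lowq_frac = 0.5) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence/quality length mismatch at record ",
         which(nchar(reads$seq) != nchar(reads$qual))[1], call. = FALSE)
  n_count <- nchar(reads$seq) - nchar(gsub("N", "", reads$seq, fixed = TRUE))
  lowq_frac <- vapply(reads$qual, function(q) {
    ph <- utf8ToInt(q) - 33L
    mean(ph < min_phred)
  }, numeric(1), USE.NAMES = FALSE)
  fail_n <- n_count > max_n
  fail_q <- lowq_frac > max_lowq_frac
  drop <- fail_n | fail_q
  list(
    reads = reads[!drop, , drop = FALSE],
    report = list(
      n_input = nrow(reads),
      n_kept = sum(!drop),
      n_dropped = sum(drop),
      n_dropped_n = sum(fail_n),
      n_dropped_quality = sum(fail_q)
    )
  )
}
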