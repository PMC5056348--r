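#' Emit aligned fragments and FASTQ reads realizing a depth matrix
#'
#' For every CpG site and sample, emits exactly `depth[site, sample]`
#' fragments overlapping that site's dinucleotide, so total fragments per
#' sample equal the depth column sum.  In `exact_cover` mode (config
#' default) each fragment is clipped to overlap only its own CpG, making
#' [cpg_depth()] an exact inverse; otherwise fragments take sonication
#' lengths from `frag_len_range` and may span neighbouring CpGs.  A
#' `multi_hit_rate` fraction of fragments receives decoy alignments at
#' random coordinates (same read id, `n_hits` > 1) for the duplicate
#' collapser, and the paired FASTQ gets configured fractions of reads
#' violating the N / low-quality rules.
#'
#' @param depths A raw [depth_matrix()] from [simulate_depths()].
#' @param genome The `genome_model` the depths were simulated on.
#' @param config The [sim_config()].
#' @return List with `reads` (data.frame id, chrom, start, end, strand,
#'   n_hits, sample; primary and decoy alignment records) and `fastq`
#'   (data.frame id, seq, qual, sample; one record per fragment).
#' @export
emit_reads <- function(depths, genome, config) {
  validate_sim_config(config)
  dm <- depths
  lens <- genome$chrom_lengths
  with_seed(config$seed + 3L, {
    read_list <- vector("list", ncol(dm$depth))
    fq_list <- vector("list", ncol(dm$depth))
    for (j in seq_len(ncol(dm$depth))) {
      d <- dm$depth[, j]
      idx <- rep.int(seq_along(d), d)
      n_frag <- length(idx)
      if (n_frag == 0) {
        read_list[[j]] <- fq_list[[j]] <- NULL
        next
      }
      pos <- dm$pos[idx]
      chrom <- dm$chrom[idx]
      clen <- as.integer(lens[chrom])
      maxlen <- config$frag_len_range[2]
      if (config$exact_cover) {
        # clip each fragment between its neighbouring CpG dinucleotides
        prev_ok <- c(FALSE, dm$chrom[-1] == dm$chrom[-length(dm$chrom)])
        lo_site <- ifelse(prev_ok, c(-1L, dm$pos[-length(dm$pos)]) + 2L, 0L)
        next_ok <- c(dm$chrom[-1] == dm$chrom[-length(dm$chrom)], FALSE)
        hi_site <- ifelse(next_ok, c(dm$pos[-1], -1L),
                          as.integer(lens[dm$chrom]))
        lo <- pmax(lo_site[idx], pos - maxlen)
        hi <- pmin(hi_site[idx], pos + 2L + maxlen)
        start <- lo + floor(runif(n_frag) * (pos - lo + 1L))
        end <- pos + 2L + floor(runif(n_frag) * (hi - pos - 1L))
      } else {
        flen <- config$frag_len_range[1] +
          floor(runif(n_frag) * (diff(config$frag_len_range) + 1L))
        start <- pos + 2L - flen + floor(runif(n_frag) * (flen - 1L))
        start <- pmax(0L, pmin(start, clen - flen))
        end <- start + flen
      }
      id <- sprintf("%s_f%06d", dm$samples$sample[j], seq_len(n_frag))
      strand <- ifelse(runif(n_frag) < 0.5, "+", "-")
      extra <- rbinom(n_frag, 1L, config$multi_hit_rate)
      n_hits <- 1L + extra * (1L + rpois(n_frag, 0.5))
      prim <- data.frame(id = id, chrom = chrom, start = as.integer(start),
                         end = as.integer(end), strand = strand,
                         n_hits = n_hits, sample = dm$samples$sample[j],
                         stringsAsFactors = FALSE)
      dup_idx <- rep.int(which(n_hits > 1L), pmax(n_hits - 1L, 0L)[n_hits > 1L])
      if (length(dup_idx)) {
        w <- prim$end[dup_idx] - prim$start[dup_idx]
        dchrom <- names(lens)[1L + floor(runif(length(dup_idx)) * length(lens))]
        dstart <- floor(runif(length(dup_idx)) *
                          pmax(as.integer(lens[dchrom]) - w, 1L))
        decoy <- data.frame(id = prim$id[dup_idx], chrom = dchrom,
                            start = as.integer(dstart),
                            end = as.integer(dstart + w),
                            strand = prim$strand[dup_idx],
                            n_hits = prim$n_hits[dup_idx],
                            sample = prim$sample[dup_idx],
                            stringsAsFactors = FALSE)
        reads <- rbind(prim, decoy)
      } else reads <- prim
      read_list[[j]] <- reads

      # FASTQ: random bases, Q40 baseline, injected QC violations
      L <- config$read_length
      base_mat <- matrix(c("A", "C", "G", "T")[1L + floor(runif(n_frag * L) * 4)],
                         nrow = n_frag)
      qual <- rep(strrep(rawToChar(as.raw(33L + 40L)), L), n_frag)
      n_bad_n <- floor(n_frag * config$n_inject_rate)
      n_bad_q <- floor(n_frag * config$lowq_rate)
      pick <- sample.int(n_frag, min(n_frag, n_bad_n + n_bad_q))
      set_n <- pick[seq_len(n_bad_n)]
      set_q <- setdiff(pick, set_n)
      for (i in set_n) {  # > 5 Ns
        k <- min(L, 6L + floor(runif(1) * 3))
        base_mat[i, sample.int(L, k)] <- "N"
      }
      lowq_char <- rawToChar(as.raw(33L + 2L))  # Phred 2 < 5
      for (i in set_q) {  # > 50% of bases below Phred 5
        k <- floor(L / 2) + 1L
        q <- strsplit(qual[i], "")[[1]]
        q[sample.int(L, k)] <- lowq_char
        qual[i] <- paste(q, collapse = "")
      }
      fq_list[[j]] <- data.frame(
        id = id, seq = apply(base_mat, 1, paste, collapse = ""),
        qual = qual, sample = dm$samples$sample[j], stringsAsFactors = FALSE
      )
    }
    list(reads = do.call(rbind, read_list), fastq = do.call(rbind, fq_list))
  })
}

#' Write aligned reads as per-sample BED6 files
#'
#' The BED name field carries the alignment hit count as `<id>/<n_hits>`;
#' score repeats `n_hits`.
#'
#' @param reads data.frame as returned in `emit_reads()$reads`.
#' @param dir Output directory.
#' @return Written paths, invisibly.
#' @export
write_reads_bed <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in unique(reads$sample)) {
    r <- reads[reads$sample == s, ]
    p <- file.path(dir, paste0(s, ".bed"))
    write.table(
      data.frame(r$chrom, r$start, r$end,
                 paste0(r$id, "/", r$n_hits), r$n_hits, r$strand),
      p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write FASTQ records
#'
#' @param fastq data.frame with id, seq, qual (as in `emit_reads()$fastq`).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(fastq, path) {
  seqs <- Biostrings::DNAStringSet(fastq$seq)
  names(seqs) <- fastq$id
  withCallingHandlers(
    Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                qualities = Biostrings::BStringSet(fastq$qual)),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  invisible(path)
}
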