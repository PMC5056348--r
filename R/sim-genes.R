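#' Gene model container
#'
#' @param genes data.frame with gene_id, chrom, start, end (0-based
#'   half-open span), strand ('+'/'-').  TSS/TES coordinates are derived:
#'   on '+' the TSS is `start` and TES `end`; on '-' the TSS is `end` and
#'   TES `start` (half-open convention, so flanks are `[TSS, TSS+f)` etc.).
#' @param exons data.frame with gene_id, chrom, start, end; every exon must
#'   lie within its gene's span.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  m <- match(exons$gene_id, genes$gene_id)
  if (any(is.na(m))) stop("exon references unknown gene")
  if (any(exons$start < genes$start[m] | exons$end > genes$end[m]))
    stop("exon outside gene span")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  structure(list(genes = genes, exons = exons), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Simulate gene models on a synthetic genome
#'
#' Places non-overlapping gene spans (kept >= 4 kb apart so promoter and
#' downstream flanks rarely collide), random strands, and 1-6 exons per
#' gene with the first and last exon anchored at the gene ends.
#'
#' @param genome A `genome_model`.
#' @param n_genes Number of genes to attempt.
#' @param length_range Gene span range in bp.
#' @param seed RNG seed.
#' @return A [gene_model()].
#' @export
simulate_genes <- function(genome, n_genes = 150L,
                           length_range = c(2000L, 20000L), seed = 1L) {
  lens <- genome$chrom_lengths
  with_seed(seed, {
    genes <- list(); exons <- list(); placed <- 0L
    occ <- lapply(names(lens), function(ch) cbind(numeric(0), numeric(0)))
    names(occ) <- names(lens)
    tries <- 0L
    while (placed < n_genes && tries < n_genes * 50L) {
      tries <- tries + 1L
      ch <- names(lens)[1L + floor(runif(1) * length(lens))]
      L <- as.integer(floor(runif(1, length_range[1], length_range[2] + 1)))
      if (lens[ch] < L + 8000) next
      s <- as.integer(floor(runif(1, 4000, lens[ch] - L - 4000)))
      o <- occ[[ch]]
      if (nrow(o) > 0 && any(o[, 1] < s + L + 4000 & o[, 2] > s - 4000)) next
      placed <- placed + 1L
      gid <- sprintf("gene%04d", placed)
      strand <- if (runif(1) < 0.5) "+" else "-"
      occ[[ch]] <- rbind(o, c(s, s + L))
      genes[[placed]] <- data.frame(gene_id = gid, chrom = ch, start = s,
                                    end = s + L, strand = strand,
                                    stringsAsFactors = FALSE)
      n_ex <- 1L + floor(runif(1) * 6)
      if (n_ex == 1L || L < 2L * (2L * n_ex - 1L)) {
        exons[[placed]] <- data.frame(gene_id = gid, chrom = ch,
                                      start = s, end = s + L,
                                      stringsAsFactors = FALSE)
      } else {
        w <- stats::rexp(2L * n_ex - 1L) + 0.05
        w <- as.integer(floor(w / sum(w) * L))
        w[w < 1] <- 1L
        w[1] <- L - sum(w[-1])
        if (w[1] < 1) { w <- rep(L %/% (2L * n_ex - 1L), 2L * n_ex - 1L)
                        w[1] <- L - sum(w[-1]) }
        b <- as.integer(s + c(0L, cumsum(w)))
        ex_idx <- seq(1L, 2L * n_ex - 1L, by = 2L)
        exons[[placed]] <- data.frame(gene_id = gid, chrom = ch,
                                      start = b[ex_idx], end = b[ex_idx + 1L],
                                      stringsAsFactors = FALSE)
      }
    }
    gene_model(do.call(rbind, genes), do.call(rbind, exons))
  })
}

#' Write / read gene models as GTF
#'
#' @param gm A [gene_model()].
#' @param path GTF file path.
#' @return `write_genes_gtf()` returns `path` invisibly;
#'   `read_gene_models()` a `gene_model` (accepts GTF/GFF or BED12 by
#'   extension).
#' @export
write_genes_gtf <- function(gm, path) {
  g <- gm$genes; e <- gm$exons
  gr_g <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end),
                                 strand = g$strand)
  gr_g$type <- "gene"; gr_g$gene_id <- g$gene_id
  gr_g$transcript_id <- paste0(g$gene_id, ".t1")
  es <- g$strand[match(e$gene_id, g$gene_id)]
  gr_e <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start + 1L, e$end),
                                 strand = es)
  gr_e$type <- "exon"; gr_e$gene_id <- e$gene_id
  gr_e$transcript_id <- paste0(e$gene_id, ".t1")
  gr <- c(gr_g, gr_e)
  gr$source <- "medipdmr"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_genes_gtf
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff2", "gff3")) {
    gr <- rtracklayer::import(path)
    gg <- gr[gr$type == "gene"]
    ge <- gr[gr$type == "exon"]
    genes <- data.frame(
      gene_id = gg$gene_id,
      chrom = as.character(GenomeInfoDb::seqnames(gg)),
      start = GenomicRanges::start(gg) - 1L,
      end = GenomicRanges::end(gg),
      strand = as.character(GenomicRanges::strand(gg)),
      stringsAsFactors = FALSE
    )
    exons <- data.frame(
      gene_id = ge$gene_id,
      chrom = as.character(GenomeInfoDb::seqnames(ge)),
      start = GenomicRanges::start(ge) - 1L,
      end = GenomicRanges::end(ge),
      stringsAsFactors = FALSE
    )
    gene_model(genes, exons)
  } else if (ext == "bed") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 12) stop("BED12 required for gene models")
    names(df)[1:12] <- c("chrom", "start", "end", "name", "score", "strand",
                         "thickStart", "thickEnd", "rgb", "blockCount",
                         "blockSizes", "blockStarts")
    genes <- data.frame(gene_id = df$name, chrom = df$chrom, start = df$start,
                        end = df$end, strand = df$strand,
                        stringsAsFactors = FALSE)
    exons <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      sz <- as.integer(strsplit(df$blockSizes[i], ",")[[1]])
      st <- as.integer(strsplit(df$blockStarts[i], ",")[[1]])
      data.frame(gene_id = df$name[i], chrom = df$chrom[i],
                 start = df$start[i] + st, end = df$start[i] + st + sz,
                 stringsAsFactors = FALSE)
    }))
    gene_model(genes, exons)
  } else stop("unsupported gene model format: ", ext)
}

#' Write a gene model as BED12
#'
#' @param gm A [gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_bed12 <- function(gm, path) {
  g <- gm$genes
  rows <- lapply(seq_len(nrow(g)), function(i) {
    e <- gm$exons[gm$exons$gene_id == g$gene_id[i], , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    data.frame(g$chrom[i], g$start[i], g$end[i], g$gene_id[i], 0L,
               g$strand[i], g$start[i], g$end[i], "0,0,0", nrow(e),
               paste0(paste(e$end - e$start, collapse = ","), ","),
               paste0(paste(e$start - g$start[i], collapse = ","), ","),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
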