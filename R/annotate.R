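# Annotation of DMRs to the five canonical gene features.

FEATURE_ORDER <- c("promoter", "exon", "intron", "downstream", "intergenic")

#' Build the five canonical gene-feature interval sets
#'
#' Promoter = `promoter_bp` upstream of the TSS (strand-aware); downstream
#' = `downstream_bp` past the TES; introns = gene span minus exons;
#' intergenic = everything not covered by a gene-linked feature.  Flanks
#' are clipped at chromosome bounds.  Assignment precedence (promoter >
#' exon > intron > downstream > intergenic) is applied at
#' [assign_dmrs()] time.
#'
#' @param gm A [gene_model()].
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param promoter_bp,downstream_bp Flank sizes (default 2000).
#' @return A `feature_set`: list of [GenomicRanges::GRanges] (1-based
#'   closed, converted from the 0-based model) named by feature; genic
#'   features carry a `gene_id` metadata column.
#' @export
build_features <- function(gm, chrom_lengths, promoter_bp = 2000L,
                           downstream_bp = 2000L) {
  g <- gm$genes
  if (any(!(g$chrom %in% names(chrom_lengths))))
    stop("gene on unknown chromosome")
  if (any(g$tss < 0 | g$tss > chrom_lengths[g$chrom]))
    stop("TSS outside chromosome")
  clen <- chrom_lengths[g$chrom]
  # 0-based half-open flank intervals
  prom_s <- ifelse(g$strand == "+", pmax(0, g$tss - promoter_bp), g$tss)
  prom_e <- ifelse(g$strand == "+", g$tss, pmin(clen, g$tss + promoter_bp))
  down_s <- ifelse(g$strand == "+", g$tes, pmax(0, g$tes - downstream_bp))
  down_e <- ifelse(g$strand == "+", pmin(clen, g$tes + downstream_bp), g$tes)
  mk <- function(chrom, s, e, gene_id) {
    keep <- e > s
    gr <- GenomicRanges::GRanges(chrom[keep],
                                 IRanges::IRanges(s[keep] + 1L, e[keep]))
    GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
    gr$gene_id <- gene_id[keep]
    gr
  }
  promoter <- mk(g$chrom, prom_s, prom_e, g$gene_id)
  downstream <- mk(g$chrom, down_s, down_e, g$gene_id)
  exon <- mk(gm$exons$chrom, gm$exons$start, gm$exons$end, gm$exons$gene_id)
  # introns: per-gene span minus exons
  intron_list <- lapply(seq_len(nrow(g)), function(i) {
    span <- IRanges::IRanges(g$start[i] + 1L, g$end[i])
    ex <- gm$exons[gm$exons$gene_id == g$gene_id[i], , drop = FALSE]
    intr <- IRanges::setdiff(span, IRanges::IRanges(ex$start + 1L, ex$end))
    if (length(intr) == 0) return(NULL)
    gr <- GenomicRanges::GRanges(g$chrom[i], intr)
    GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
    gr$gene_id <- g$gene_id[i]
    gr
  })
  intron_list <- intron_list[!vapply(intron_list, is.null, logical(1))]
  intron <- if (length(intron_list)) do.call(c, intron_list) else
    mk(character(0), integer(0), integer(0), character(0))
  genic <- c(GenomicRanges::granges(promoter), GenomicRanges::granges(exon),
             GenomicRanges::granges(intron), GenomicRanges::granges(downstream))
  genome_gr <- GenomicRanges::GRanges(
    names(chrom_lengths), IRanges::IRanges(1L, as.integer(chrom_lengths)))
  intergenic <- GenomicRanges::setdiff(genome_gr,
                                       GenomicRanges::reduce(genic))
  intergenic$gene_id <- rep(NA_character_, length(intergenic))
  structure(list(promoter = promoter, exon = exon, intron = intron,
                 downstream = downstream, intergenic = intergenic),
            class = "feature_set")
}

#' Assign DMRs to gene features by precedence
#'
#' A DMR takes the highest-precedence feature it overlaps by >= 1 bp
#' (promoter > exon > intron > downstream > intergenic); for genic labels
#' all owning gene ids are attached (comma-separated when a DMR touches the
#' same feature of several genes).
#'
#' @param dmrs data.frame with chrom, start, end (0-based half-open);
#'   a `direction` column, when present, is carried through.
#' @param features A `feature_set` from [build_features()].
#' @return `dmrs` with `feature` and `gene_ids` columns appended.
#' @export
assign_dmrs <- function(dmrs, features) {
  out <- dmrs
  out$feature <- rep(NA_character_, nrow(dmrs))
  out$gene_ids <- rep(NA_character_, nrow(dmrs))
  if (nrow(dmrs) == 0) return(out)
  d_gr <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  for (f in FEATURE_ORDER) {
    open <- which(is.na(out$feature))
    if (length(open) == 0) break
    hits <- GenomicRanges::findOverlaps(d_gr[open], features[[f]])
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    gid <- features[[f]]$gene_id[sh]
    by_q <- split(gid, qh)
    hit_rows <- open[as.integer(names(by_q))]
    out$feature[hit_rows] <- f
    out$gene_ids[hit_rows] <- vapply(by_q, function(x) {
      x <- unique(x[!is.na(x)])
      if (length(x) == 0) NA_character_ else paste(sort(x), collapse = ",")
    }, character(1))
  }
  out
}

#' Annotation count table
#'
#' Builds the hyper/hypo x feature table: genic features count distinct
#' (gene, direction) pairs, the intergenic column counts DMRs.
#'
#' @param assignments data.frame from [assign_dmrs()] with `feature`,
#'   `gene_ids` and `direction` columns.
#' @return An `annotation_table` (see [annotation_table()]).
#' @export
count_table <- function(assignments) {
  counts <- matrix(0L, nrow = 2, ncol = length(FEATURE_ORDER),
                   dimnames = list(c("hyper", "hypo"), FEATURE_ORDER))
  for (dir in c("hyper", "hypo")) {
    a <- assignments[!is.na(assignments$feature) &
                       assignments$direction == dir, , drop = FALSE]
    for (f in FEATURE_ORDER) {
      af <- a[a$feature == f, , drop = FALSE]
      if (f == "intergenic") {
        counts[dir, f] <- nrow(af)
      } else {
        genes <- unique(unlist(strsplit(af$gene_ids[!is.na(af$gene_ids)], ",")))
        counts[dir, f] <- length(genes)
      }
    }
  }
  annotation_table(counts)
}

#' Construct an annotation table from feature-direction counts
#'
#' Useful both as the output container of [count_table()] and for summary
#' arithmetic on an externally reported count table.
#'
#' @param counts 2 x 5 matrix (rows hyper/hypo, columns the five features).
#' @return An `annotation_table`: list with `counts`, `feature_totals`
#'   (hyper + hypo per feature), `grand_total`, and `percent` (per-feature
#'   share of the grand total, in percent; sums to 100).
#' @export
annotation_table <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2, ncol(counts) == length(FEATURE_ORDER))
  rownames(counts) <- c("hyper", "hypo")
  colnames(counts) <- FEATURE_ORDER
  if (any(counts < 0)) stop("counts must be non-negative")
  ft <- colSums(counts)
  gt <- sum(ft)
  structure(list(counts = counts, feature_totals = ft, grand_total = gt,
                 percent = if (gt > 0) 100 * ft / gt else ft * NA_real_),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  print(x$counts)
  cat("feature shares (%):",
      paste(sprintf("%s %.1f", names(x$percent), x$percent), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write an annotation table as TSV
#'
#' @param at An `annotation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(at, path) {
  df <- data.frame(direction = rownames(at$counts), at$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of genes with hypermethylated promoters
#'
#' @param directions Character vector of per-gene promoter direction calls
#'   ("hyper"/"hypo"), or a data.frame with a `direction` column.
#' @return Percentage `100 * hyper / total`, rounded to two decimals.
#' @export
fraction_hypermethylated <- function(directions) {
  if (is.data.frame(directions)) directions <- directions$direction
  if (length(directions) == 0)
    stop("empty gene list: fraction undefined")
  if (!all(directions %in% c("hyper", "hypo")))
    stop("directions must be 'hyper' or 'hypo'")
  round(100 * mean(directions == "hyper"), 2)
}
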