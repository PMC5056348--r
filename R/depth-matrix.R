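#' CpG depth matrix
#'
#' The central object of the DMR caller: read depth at each retained CpG
#' site for each sample, with two-group labels.  Raw matrices hold integer
#' fragment counts; [normalize_depths()] rescales them to each group's mean
#' library size and sets the `normalized` flag.
#'
#' @param chrom Character vector of chromosome names per site.
#' @param pos Integer vector, 0-based position of the C of each CpG
#'   dinucleotide; sites must be sorted by (chrom, pos).
#' @param depth Numeric matrix, sites x samples, non-negative.
#' @param groups Character vector of group labels per sample (exactly two
#'   distinct labels).  "Group 1" — the group in which a DMR's direction is
#'   reported — is the first label in factor-level order (alphabetical for
#'   character labels).
#' @param lib_sizes Optional per-sample library sizes (post-collapse aligned
#'   fragment counts); defaults to column sums of `depth`.
#' @param normalized Logical flag.
#' @param scale_factors Per-sample normalization factors (1 before
#'   normalization).
#' @return An object of class `depth_matrix`.
#' @export
depth_matrix <- function(chrom, pos, depth, groups,
                         lib_sizes = NULL, normalized = FALSE,
                         scale_factors = NULL) {
  depth <- as.matrix(depth)
  stopifnot(length(chrom) == nrow(depth), length(pos) == nrow(depth),
            length(groups) == ncol(depth))
  if (any(depth < 0)) stop("depths must be non-negative")
  if (length(unique(groups)) != 2L)
    stop("depth_matrix requires exactly two groups")
  ord <- order(chrom, pos)
  if (is.unsorted(ord)) {  # reorder to canonical (chrom, pos)
    chrom <- chrom[ord]; pos <- pos[ord]; depth <- depth[ord, , drop = FALSE]
  }
  if (is.null(colnames(depth)))
    colnames(depth) <- paste0(groups, "_", stats::ave(seq_along(groups),
                                                      groups, FUN = seq_along))
  if (is.null(lib_sizes)) lib_sizes <- colSums(depth)
  if (is.null(scale_factors)) scale_factors <- rep(1, ncol(depth))
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos), depth = depth,
         samples = data.frame(sample = colnames(depth), group = groups,
                              stringsAsFactors = FALSE),
         lib_sizes = setNames(as.numeric(lib_sizes), colnames(depth)),
         normalized = normalized,
         scale_factors = setNames(as.numeric(scale_factors), colnames(depth))),
    class = "depth_matrix"
  )
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat("depth_matrix:", nrow(x$depth), "CpG sites x", ncol(x$depth),
      "samples (groups:", paste(unique(x$samples$group), collapse = ", "),
      ")", if (x$normalized) "[normalized]" else "[raw]", "\n")
  invisible(x)
}

#' @export
dim.depth_matrix <- function(x) dim(x$depth)

# Column indices of the two groups.  "Group 1" is the first label in
# factor-level order (alphabetical for plain character labels), so the
# hyper/hypo direction convention is stable under sample reordering and a
# pure label swap flips it.
group_columns <- function(dm) {
  g <- dm$samples$group
  labs <- if (is.factor(g)) levels(g) else sort(unique(g))
  list(g1 = which(dm$samples$group == labs[1]),
       g2 = which(dm$samples$group == labs[2]),
       labels = labs)
}

# subset sites by logical or integer index, preserving metadata
subset_sites <- function(dm, idx) {
  depth_matrix(dm$chrom[idx], dm$pos[idx], dm$depth[idx, , drop = FALSE],
               dm$samples$group, lib_sizes = dm$lib_sizes,
               normalized = dm$normalized, scale_factors = dm$scale_factors)
}

#' CpG sites of a depth matrix as GRanges
#'
#' @param dm A `depth_matrix`.
#' @return Width-2 [GenomicRanges::GRanges] of the member dinucleotides.
#' @export
depth_granges <- function(dm) {
  GenomicRanges::GRanges(dm$chrom, IRanges::IRanges(start = dm$pos + 1L, width = 2L))
}

#' Write / read a depth matrix as TSV
#'
#' Layout: comment header lines (`#group:`, `#libsize:`, `#normalized:`)
#' followed by columns chrom, pos, then one column per sample.
#'
#' @param dm A `depth_matrix`.
#' @param path File path.
#' @return `write_depth_matrix()` returns `path` invisibly;
#'   `read_depth_matrix()` returns a `depth_matrix`.
#' @export
write_depth_matrix <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#group: ", paste(dm$samples$group, collapse = "\t")),
    paste0("#libsize: ", paste(format(dm$lib_sizes, digits = 15, trim = TRUE),
                               collapse = "\t")),
    paste0("#normalized: ", tolower(as.character(dm$normalized))),
    paste0("#scale: ", paste(format(dm$scale_factors, digits = 15, trim = TRUE),
                             collapse = "\t"))
  ), con)
  df <- data.frame(chrom = dm$chrom, pos = dm$pos, dm$depth,
                   check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' @rdname write_depth_matrix
#' @export
read_depth_matrix <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, ":"))]
    if (length(ln) == 0) return(NULL)
    strsplit(sub(paste0("^#", key, ": ?"), "", ln[1]), "\t")[[1]]
  }
  groups <- get_field("group")
  libs <- as.numeric(get_field("libsize"))
  normalized <- identical(get_field("normalized"), "true")
  scales <- as.numeric(get_field("scale"))
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  depth <- as.matrix(df[, -(1:2), drop = FALSE])
  depth_matrix(df$chrom, df$pos, depth, groups,
               lib_sizes = setNames(libs, colnames(depth)),
               normalized = normalized,
               scale_factors = setNames(scales, colnames(depth)))
}

#' Write per-sample bedGraph tracks of a depth matrix
#'
#' One bedGraph per sample, each line covering a member CpG dinucleotide.
#'
#' @param dm A `depth_matrix`.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_bedgraphs <- function(dm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(ncol(dm$depth))
  for (j in seq_len(ncol(dm$depth))) {
    paths[j] <- file.path(dir, paste0(dm$samples$sample[j], ".bedGraph"))
    write.table(
      data.frame(dm$chrom, dm$pos, dm$pos + 2L, dm$depth[, j]),
      paths[j], sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  invisible(paths)
}
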