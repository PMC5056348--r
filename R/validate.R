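# Orthogonal-validation computations: bisulfite clone summaries, 2^-ddCt
# relative expression, fatty-acid composition, adipocyte volume.

#' Summarize a bisulfite-sequencing clone matrix
#'
#' Each row is one sequenced subclone, each column a CpG site; 1 =
#' methylated (protected C), 0 = unmethylated (converted to T).  Reports
#' per-site percent methylation, the region mean, and a text lollipop
#' rendering (filled circle = methylated).
#'
#' @param clone_matrix Binary matrix (clones x sites) or data.frame.
#' @return List with `site_pct`, `region_pct`, `n_clones`, `lollipop`
#'   (one string per clone).
#' @export
bsp_summary <- function(clone_matrix) {
  m <- as.matrix(clone_matrix)
  if (length(m) == 0 || nrow(m) == 0 || ncol(m) == 0)
    stop("empty clone matrix")
  if (!all(m %in% c(0, 1))) stop("clone matrix must be binary")
  site_pct <- 100 * colMeans(m)
  lollipop <- apply(m, 1, function(r)
    paste(ifelse(r == 1, "●", "○"), collapse = ""))
  list(site_pct = site_pct, region_pct = mean(site_pct),
       n_clones = nrow(m), lollipop = unname(lollipop))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per (sample, gene): dCt = mean target Ct - mean reference Ct, the
#' reference aggregated as the arithmetic mean of the reference genes' Ct
#' (equivalent to a geometric mean of reference quantities).  ddCt
#' subtracts the calibrator group's mean dCt for that gene, and relative
#' expression is 2^-ddCt, so the calibrator group's geometric mean
#' expression is 1.
#'
#' @param ct_table Long data.frame with columns `sample`, `group`, `gene`,
#'   `ct` (one row per technical replicate).
#' @param reference_genes Internal-control genes; every sample must carry
#'   all of them.  Defaults to the standard mRNA panel ACTB, TBP, TOP2B
#'   (use "U6" for miRNA assays).
#' @param calibrator_group Group whose mean dCt anchors ddCt; default the
#'   second group label in the table.
#' @return data.frame with sample, group, gene, delta_ct, delta_delta_ct,
#'   rel_expr for every non-reference gene.
#' @export
ddct <- function(ct_table, reference_genes = c("ACTB", "TBP", "TOP2B"),
                 calibrator_group = NULL) {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(ct_table)))
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  groups <- unique(ct_table$group)
  if (is.null(calibrator_group)) calibrator_group <- groups[length(groups)]
  if (!calibrator_group %in% groups) stop("unknown calibrator group")
  agg <- stats::aggregate(ct ~ sample + group + gene, ct_table, mean)
  ref <- agg[agg$gene %in% reference_genes, , drop = FALSE]
  missing_ref <- vapply(unique(agg$sample), function(s)
    !all(reference_genes %in% ref$gene[ref$sample == s]), logical(1))
  if (any(missing_ref))
    stop("missing reference gene(s) for sample(s): ",
         paste(unique(agg$sample)[missing_ref], collapse = ", "))
  ref_ct <- stats::aggregate(ct ~ sample, ref, mean)
  tgt <- agg[!(agg$gene %in% reference_genes), , drop = FALSE]
  tgt$delta_ct <- tgt$ct - ref_ct$ct[match(tgt$sample, ref_ct$sample)]
  calib <- tgt[tgt$group == calibrator_group, , drop = FALSE]
  calib_mean <- stats::aggregate(delta_ct ~ gene, calib, mean)
  tgt$delta_delta_ct <- tgt$delta_ct -
    calib_mean$delta_ct[match(tgt$gene, calib_mean$gene)]
  tgt$rel_expr <- 2^(-tgt$delta_delta_ct)
  tgt[, c("sample", "group", "gene", "delta_ct", "delta_delta_ct", "rel_expr")]
}

#' Default fatty-acid species-to-class map
#'
#' @return Named character vector mapping common species (C14:0 ... C22:6)
#'   to SFA / MUFA / PUFA.
#' @export
fatty_acid_classes <- function() {
  c("C10:0" = "SFA", "C12:0" = "SFA", "C14:0" = "SFA", "C15:0" = "SFA",
    "C16:0" = "SFA", "C17:0" = "SFA", "C18:0" = "SFA", "C20:0" = "SFA",
    "C22:0" = "SFA", "C24:0" = "SFA",
    "C14:1" = "MUFA", "C16:1" = "MUFA", "C17:1" = "MUFA", "C18:1" = "MUFA",
    "C20:1" = "MUFA", "C22:1" = "MUFA", "C24:1" = "MUFA",
    "C18:2n-6" = "PUFA", "C18:3n-3" = "PUFA", "C18:3n-6" = "PUFA",
    "C20:2" = "PUFA", "C20:3n-3" = "PUFA", "C20:3n-6" = "PUFA",
    "C20:4n-6" = "PUFA", "C20:5n-3" = "PUFA", "C22:2" = "PUFA",
    "C22:4" = "PUFA", "C22:5" = "PUFA", "C22:6" = "PUFA")
}

#' Fatty-acid composition summary
#'
#' Sums each sample's species percentages into SFA / MUFA / PUFA classes,
#' reports group mean class shares and the PUFA:SFA ratio (computed on the
#' group mean sums, rounded to two decimals — dietary guidance recommends
#' > 0.4), and compares class totals between groups with a two-sided
#' Student's t-test (unpaired by default).
#'
#' @param fa Long data.frame with `sample`, `group`, `species`, `pct`
#'   (percent of total fatty acids; per-sample sums should be ~100).
#' @param classes Named species-to-class map; default
#'   [fatty_acid_classes()].
#' @param paired Use a paired t-test for the group contrasts.
#' @return List with `per_sample` (class sums per sample), `group_means`,
#'   `pufa_sfa_ratio` (named by group; NA with a warning if an SFA sum is
#'   zero), and `tests` (per-class t-test p-values, NA when group sizes
#'   do not permit the test).
#' @export
fatty_acid_summary <- function(fa, classes = fatty_acid_classes(),
                               paired = FALSE) {
  stopifnot(all(c("sample", "group", "species", "pct") %in% names(fa)))
  unknown <- setdiff(unique(fa$species), names(classes))
  if (length(unknown))
    stop("unclassed species: ", paste(unknown, collapse = ", "))
  fa$class <- classes[fa$species]
  tot <- stats::aggregate(pct ~ sample, fa, sum)
  off <- abs(tot$pct - 100) > 2
  if (any(off))
    warning("per-sample percentages deviate from 100 by > 2: ",
            paste(tot$sample[off], collapse = ", "))
  per_sample <- stats::aggregate(pct ~ sample + group + class, fa, sum)
  group_means <- stats::aggregate(pct ~ group + class, per_sample, mean)
  groups <- unique(fa$group)
  ratio <- vapply(groups, function(g) {
    sfa <- group_means$pct[group_means$group == g & group_means$class == "SFA"]
    pufa <- group_means$pct[group_means$group == g & group_means$class == "PUFA"]
    if (length(sfa) == 0 || sfa == 0) {
      warning("SFA sum is zero for group ", g, "; PUFA:SFA ratio undefined")
      return(NA_real_)
    }
    if (length(pufa) == 0) pufa <- 0
    round(pufa / sfa, 2)
  }, numeric(1))
  names(ratio) <- groups
  tests <- setNames(rep(NA_real_, 3), c("SFA", "MUFA", "PUFA"))
  if (length(groups) == 2) {
    for (cl in names(tests)) {
      x <- per_sample$pct[per_sample$class == cl & per_sample$group == groups[1]]
      y <- per_sample$pct[per_sample$class == cl & per_sample$group == groups[2]]
      if (length(x) >= 2 && length(y) >= 2 && (!paired || length(x) == length(y)))
        tests[cl] <- tryCatch(stats::t.test(x, y, paired = paired)$p.value,
                              error = function(e) NA_real_)
    }
  }
  list(per_sample = per_sample, group_means = group_means,
       pufa_sfa_ratio = ratio, tests = tests)
}

#' Mean adipocyte volume from a diameter histogram
#'
#' Count-weighted sphere volume: `V = sum(fi * pi/6 * Di^3) / sum(fi)`,
#' with `Di` the bin mean diameter (um) and `fi` the absolute cell count.
#'
#' @param diameter Bin mean diameters in micrometres (> 0).
#' @param count Absolute cell counts per bin (>= 0, positive total).
#' @return Mean adipocyte volume in cubic micrometres.
#' @export
adipocyte_volume <- function(diameter, count) {
  if (any(diameter <= 0)) stop("diameters must be positive")
  if (any(count < 0) || sum(count) == 0)
    stop("counts must be non-negative with positive total")
  sum(count * (pi / 6) * diameter^3) / sum(count)
}

#' Readers for validation tables
#'
#' TSV readers (comment lines starting with `#` are skipped) for the clone
#' matrix (clones x sites, header row of site labels), the long-format Ct
#' table (`sample`, `group`, `gene`, `ct`) and the long-format fatty-acid
#' table (`sample`, `group`, `species`, `pct`).
#'
#' @param path TSV path.
#' @return data.frame (clone matrix: numeric matrix).
#' @export
read_clone_matrix <- function(path) {
  as.matrix(read.delim(path, comment.char = "#", check.names = FALSE))
}

#' @rdname read_clone_matrix
#' @export
read_ct_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname read_clone_matrix
#' @export
read_fatty_acid_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}
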