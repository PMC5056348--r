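#!/usr/bin/env Rscript
# Genome-scale methylome description on the landscape dataset: window
# tracks, chromosome-level correlations of methylation with length / GC /
# CpG_o/e, the gene-body metaprofile, and hierarchical clustering of
# samples on planted-DMR depths.
suppressMessages(library(medipdmr))

out <- "results/profiles"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_genome("results/sim/landscape")
dm <- normalize_depths(filter_low_coverage(
  read_depth_matrix("results/sim/landscape/depths_raw.tsv")))
truth <- read_truth("results/sim/landscape/truth.bed")
genes <- read_gene_models("results/sim/landscape/genes.gtf")

# window track (100 kb windows on this reduced genome; the same operation
# with window_bp = 1e6 produces the usual megabase smoothing)
wp <- window_profile(dm, genome, window_bp = 1e5)
write.table(wp, file.path(out, "window_profile.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("window profile: %d windows, %d with CpGs\n",
            nrow(wp), sum(wp$n_cpg > 0)))

cors <- chromosome_correlations(wp)
write.table(cors, file.path(out, "chromosome_correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("chromosome-level Pearson correlations of methylation with:\n")
for (i in seq_len(nrow(cors)))
  cat(sprintf("  %-7s r = %+.3f (p = %.3g)\n",
              cors$feature[i], cors$r[i], cors$p[i]))

mp <- gene_metaprofile(dm, genes)
write.table(mp, file.path(out, "gene_metaprofile.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
g1col <- grep("^group_", names(mp), value = TRUE)[1]
cat(sprintf("gene metaprofile: %d bins; mean body depth %.1f, mean flank depth %.1f\n",
            nrow(mp), mean(mp[[g1col]][mp$zone == "body"], na.rm = TRUE),
            mean(mp[[g1col]][mp$zone != "body"], na.rm = TRUE)))

cl <- cluster_samples(dm, truth)
write.table(round(cl$cor, 4), file.path(out, "sample_correlations.tsv"),
            sep = "\t", quote = FALSE)
grp <- dm$samples$group
w <- cl$cor[outer(grp, grp, "==") & upper.tri(cl$cor)]
b <- cl$cor[outer(grp, grp, "!=") & upper.tri(cl$cor)]
cat(sprintf("clustering on planted-DMR depths: within-group r %.2f-%.2f, between-group r %.2f-%.2f\n",
            min(w), max(w), min(b), max(b)))
hc <- cl$hclust
cat("dendrogram merge order:", paste(hc$labels[hc$order], collapse = " "), "\n")
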