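#!/usr/bin/env Rscript
# Generate every synthetic input the downstream steps consume:
#  - reads/     a small read-level dataset (FASTQ + per-sample BED6
#               alignments) to exercise the QC -> depth pipeline end to end
#  - dmr/       the full-scale two-group depth matrix with 50 planted DMRs
#               at the study design (3 vs 3, depth 30, NB dispersion 0.2)
#  - landscape/ a multi-chromosome dataset with MeDIP-like CpG-density
#               enrichment and site-level methylation heterogeneity, for
#               the genome-scale profiles
suppressMessages(library(medipdmr))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## read-level dataset (small genome so the emitted files stay light) --------
cfg_reads <- sim_config(seed = 11, chrom_lengths = c(chr1 = 8e4, chr2 = 4e4),
                        n_dmrs = 4, n_inject_rate = 0.02, lowq_rate = 0.02,
                        multi_hit_rate = 0.05)
g_reads <- make_genome(cfg_reads)
t_reads <- plant_dmrs(g_reads, cfg_reads)
d_reads <- simulate_depths(g_reads, t_reads, cfg_reads)
er <- emit_reads(d_reads, g_reads, cfg_reads)
dir.create(file.path(out, "reads"), showWarnings = FALSE)
write_genome(g_reads, file.path(out, "reads"))
write_truth(t_reads, file.path(out, "reads", "truth.bed"))
write_depth_matrix(d_reads, file.path(out, "reads", "true_depths.tsv"))
write_reads_bed(er$reads, file.path(out, "reads"))
write_fastq(er$fastq, file.path(out, "reads", "reads.fastq"))
write_sim_config(cfg_reads, file.path(out, "reads", "config.yaml"))
cat(sprintf("reads/: %d CpG sites, %d fragments (%d alignment records), %d FASTQ reads\n",
            nrow(g_reads$sites), sum(d_reads$depth), nrow(er$reads),
            nrow(er$fastq)))

## full-scale DMR dataset (the study conditions) ----------------------------
cfg_dmr <- sim_config(seed = 1)
g_dmr <- make_genome(cfg_dmr)
t_dmr <- plant_dmrs(g_dmr, cfg_dmr)
d_dmr <- simulate_depths(g_dmr, t_dmr, cfg_dmr)
dir.create(file.path(out, "dmr"), showWarnings = FALSE)
write_genome(g_dmr, file.path(out, "dmr"))
write_truth(t_dmr, file.path(out, "dmr", "truth.bed"))
write_depth_matrix(d_dmr, file.path(out, "dmr", "depths_raw.tsv"))
write_sim_config(cfg_dmr, file.path(out, "dmr", "config.yaml"))
genes_dmr <- simulate_genes(g_dmr, n_genes = 150, seed = 1)
write_genes_gtf(genes_dmr, file.path(out, "dmr", "genes.gtf"))
write_genes_bed12(genes_dmr, file.path(out, "dmr", "genes.bed"))
cat(sprintf("dmr/: %d CpG sites, %d planted DMRs (%d hyper / %d hypo), %d genes\n",
            nrow(g_dmr$sites), nrow(t_dmr), sum(t_dmr$direction == "hyper"),
            sum(t_dmr$direction == "hypo"), nrow(genes_dmr$genes)))

## landscape dataset for genome-scale profiles ------------------------------
chroms <- setNames(as.integer(seq(1.5e6, 4e5, length.out = 8)),
                   paste0("chr", 1:8))
cfg_land <- sim_config(seed = 5, chrom_lengths = chroms,
                       gc_range = c(0.35, 0.62), density_link = 1,
                       site_sd = 0.8, n_dmrs = 50)
g_land <- make_genome(cfg_land)
t_land <- plant_dmrs(g_land, cfg_land)
d_land <- simulate_depths(g_land, t_land, cfg_land)
dir.create(file.path(out, "landscape"), showWarnings = FALSE)
write_genome(g_land, file.path(out, "landscape"))
write_truth(t_land, file.path(out, "landscape", "truth.bed"))
write_depth_matrix(d_land, file.path(out, "landscape", "depths_raw.tsv"))
write_sim_config(cfg_land, file.path(out, "landscape", "config.yaml"))
genes_land <- simulate_genes(g_land, n_genes = 250, seed = 5)
write_genes_gtf(genes_land, file.path(out, "landscape", "genes.gtf"))
cat(sprintf("landscape/: %d chromosomes, %d CpG sites, %d genes\n",
            length(chroms), nrow(g_land$sites), nrow(genes_land$genes)))
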