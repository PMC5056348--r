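#!/usr/bin/env Rscript
# Raw reads -> filtered, normalized CpG depth matrix, on the read-level
# dataset from 01_simulate.R: FASTQ quality filtering (>5 Ns or Phred<5 on
# >50% of bases), multi-hit alignment collapsing, per-CpG fragment depth,
# the >= 10x group-mean coverage filter, and group-wise library-size
# normalization.  Finishes by checking the counted depths against the
# simulator's ground-truth matrix.
suppressMessages(library(medipdmr))

sim <- "results/sim/reads"
out <- "results/preprocess"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

qc <- qc_filter(file.path(sim, "reads.fastq"))
cat(sprintf("QC: %d reads in, %d kept, %d dropped (%d N-rule, %d quality-rule)\n",
            qc$report$n_input, qc$report$n_kept, qc$report$n_dropped,
            qc$report$n_dropped_n, qc$report$n_dropped_quality))

cfg <- read_sim_config(file.path(sim, "config.yaml"))
samples <- paste0(rep(cfg$group_names, each = cfg$n_samples_per_group), "_",
                  rep(seq_len(cfg$n_samples_per_group), 2))
aln <- do.call(rbind, lapply(samples, function(s)
  read_aligned_bed(file.path(sim, paste0(s, ".bed")), s)))
aln <- filter_aligned_by_qc(aln, qc$reads$id)
coll <- collapse_duplicates(aln)
cat(sprintf("alignments: %d records -> %d fragments after collapsing %d multi-hit reads\n",
            nrow(aln), nrow(coll), attr(coll, "n_collapsed")))

genome <- read_genome(sim)
groups <- setNames(rep(cfg$group_names, each = cfg$n_samples_per_group),
                   samples)
dm_raw <- cpg_depth(coll, genome, groups)
dm_filt <- filter_low_coverage(dm_raw, min_depth = 10)
dm_norm <- normalize_depths(dm_filt)
cat(sprintf("depth matrix: %d sites counted, %d retained at >= 10x group mean\n",
            nrow(dm_raw$depth), nrow(dm_filt$depth)))
cat("normalization factors:",
    paste(sprintf("%s %.3f", names(dm_norm$scale_factors),
                  dm_norm$scale_factors), collapse = ", "), "\n")

write_depth_matrix(dm_norm, file.path(out, "matrix.tsv"))
write_bedgraphs(dm_norm, file.path(out, "bedgraph"))

# cross-check against the simulator's truth: at ~30x depth, the ~4% of
# fragments dropped by QC (plus multi-hit reads collapsed to a decoy
# location) touch most cells, so the counted matrix should sit slightly
# below the simulated one but track it near-perfectly
truth_dm <- read_depth_matrix(file.path(sim, "true_depths.tsv"))
dd <- dm_raw$depth - truth_dm$depth
cat(sprintf("round-trip vs simulated truth: correlation %.4f, mean deviation %+0.2f reads/cell (QC drop rate %.1f%%)\n",
            cor(as.vector(dm_raw$depth), as.vector(truth_dm$depth)),
            mean(dd), 100 * qc$report$n_dropped / qc$report$n_input))
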