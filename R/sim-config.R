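#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  Defaults describe
#' the study design the pipeline is built for: two breeds x 3 biological
#' replicates of MeDIP-seq backfat libraries, ~30x expected depth per CpG,
#' negative-binomial overdispersion, and 50 planted 10-CpG DMRs at a 3-fold
#' depth ratio (half hyper-, half hypomethylated in group 1).
#'
#' @param seed Integer RNG seed; every generator call is deterministic given
#'   the same config (including its seed).
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param window_bp GC/CpG_o/e track window size in bp.
#' @param gc_range Length-2 numeric; per-chromosome baseline GC fractions are
#'   spread across this range, shorter chromosomes GC-richer (as in mammalian
#'   genomes), and per-window GC jitters around the baseline.
#' @param gc_jitter_sd SD of per-window GC jitter (clipped to \[0,1\]).
#' @param cpg_oe Mean per-window observed/expected CpG ratio.
#' @param cpg_oe_sd SD of per-window CpG_o/e jitter (clipped at 0).
#' @param n_samples_per_group Biological replicates per group (default 3).
#' @param group_names Length-2 character; group 1 is the "effect" group in
#'   which planted hypermethylated regions have elevated depth.
#' @param baseline_mean Expected read depth per CpG site.
#' @param dispersion Negative-binomial dispersion a, with variance
#'   mu + a*mu^2; 0 gives Poisson depths.
#' @param density_link Exponent g linking depth to local CpG density: the
#'   site mean is scaled by (window CpG density / genome mean density)^g.
#'   0 (default) gives a flat baseline; 1 makes depth proportional to local
#'   CpG density, mimicking MeDIP enrichment of CpG-dense DNA.
#' @param site_sd Log-scale SD of a per-site methylation multiplier shared
#'   by all samples (lognormal, mean 1).  0 (default) keeps every
#'   non-region site at exactly the baseline mean; positive values emulate
#'   the site-to-site methylation heterogeneity real methylomes show, which
#'   is what makes replicate samples correlate along the genome.
#' @param n_dmrs Number of planted DMRs.
#' @param dmr_n_cpg CpG sites per planted DMR.
#' @param dmr_length_bp Maximum genomic span of a planted DMR.
#' @param dmr_max_gap_bp Maximum gap between consecutive CpGs inside a
#'   planted DMR (planted regions are CpG-dense by construction).
#' @param dmr_effect Multiplicative group-1/group-2 depth ratio inside
#'   hypermethylated planted regions; hypomethylated regions use 1/effect.
#' @param dmr_hypo_fraction Fraction of planted DMRs hypomethylated in
#'   group 1.
#' @param frag_len_range Sonication fragment length range in bp.
#' @param read_length Read length for emitted FASTQ records.
#' @param n_inject_rate Fraction of FASTQ reads given >5 'N' bases (fail the
#'   QC N-rule).
#' @param lowq_rate Fraction of FASTQ reads given Phred<5 on >50% of bases
#'   (fail the QC quality rule).
#' @param multi_hit_rate Fraction of fragments aligned to multiple genomic
#'   locations (duplicates to be collapsed downstream).
#' @param exact_cover If TRUE (default) emitted fragments are clipped so each
#'   overlaps only its own CpG dinucleotide, making depth quantification an
#'   exact round-trip; if FALSE fragments take realistic sonication lengths.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 2e6, chr2 = 1.5e6, chr3 = 5e5),
                       window_bp = 10000L,
                       gc_range = c(0.38, 0.58),
                       gc_jitter_sd = 0.03,
                       cpg_oe = 0.25,
                       cpg_oe_sd = 0.05,
                       n_samples_per_group = 3L,
                       group_names = c("g1", "g2"),
                       baseline_mean = 30,
                       dispersion = 0.2,
                       density_link = 0,
                       site_sd = 0,
                       n_dmrs = 50L,
                       dmr_n_cpg = 10L,
                       dmr_length_bp = 2000L,
                       dmr_max_gap_bp = 200L,
                       dmr_effect = 3,
                       dmr_hypo_fraction = 0.5,
                       frag_len_range = c(100L, 500L),
                       read_length = 50L,
                       n_inject_rate = 0.01,
                       lowq_rate = 0.01,
                       multi_hit_rate = 0.05,
                       exact_cover = TRUE) {
  cfg <- list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    window_bp = as.integer(window_bp), gc_range = gc_range,
    gc_jitter_sd = gc_jitter_sd, cpg_oe = cpg_oe, cpg_oe_sd = cpg_oe_sd,
    n_samples_per_group = as.integer(n_samples_per_group),
    group_names = group_names, baseline_mean = baseline_mean,
    dispersion = dispersion, density_link = density_link,
    site_sd = site_sd, n_dmrs = as.integer(n_dmrs), dmr_n_cpg = as.integer(dmr_n_cpg),
    dmr_length_bp = as.integer(dmr_length_bp),
    dmr_max_gap_bp = as.integer(dmr_max_gap_bp),
    dmr_effect = dmr_effect, dmr_hypo_fraction = dmr_hypo_fraction,
    frag_len_range = as.integer(frag_len_range),
    read_length = as.integer(read_length),
    n_inject_rate = n_inject_rate, lowq_rate = lowq_rate,
    multi_hit_rate = multi_hit_rate, exact_cover = exact_cover
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.null(names(cfg$chrom_lengths)) || any(!nzchar(names(cfg$chrom_lengths))))
    stop("chrom_lengths must be a named vector", call. = FALSE)
  if (any(cfg$chrom_lengths <= 0))
    stop("invalid config: non-positive chromosome length", call. = FALSE)
  if (cfg$window_bp <= 0) stop("invalid config: window_bp must be positive", call. = FALSE)
  if (any(cfg$gc_range < 0) || any(cfg$gc_range > 1))
    stop("invalid config: gc_range outside [0,1]", call. = FALSE)
  if (cfg$cpg_oe < 0) stop("invalid config: cpg_oe must be >= 0", call. = FALSE)
  if (cfg$n_samples_per_group < 1)
    stop("invalid config: n_samples_per_group must be positive", call. = FALSE)
  if (length(cfg$group_names) != 2L)
    stop("invalid config: exactly two groups required", call. = FALSE)
  if (cfg$baseline_mean <= 0) stop("invalid config: baseline_mean must be positive", call. = FALSE)
  if (cfg$dispersion < 0) stop("invalid config: dispersion must be >= 0", call. = FALSE)
  if (cfg$site_sd < 0) stop("invalid config: site_sd must be >= 0", call. = FALSE)
  if (cfg$n_dmrs < 0 || cfg$dmr_n_cpg < 1)
    stop("invalid config: DMR counts must be positive", call. = FALSE)
  if (cfg$dmr_effect <= 0) stop("invalid config: dmr_effect must be > 0", call. = FALSE)
  if (cfg$dmr_effect == 1 && cfg$n_dmrs > 0)
    stop("invalid config: dmr_effect must differ from 1", call. = FALSE)
  if (cfg$dmr_hypo_fraction < 0 || cfg$dmr_hypo_fraction > 1)
    stop("invalid config: dmr_hypo_fraction outside [0,1]", call. = FALSE)
  if (cfg$read_length < 1) stop("invalid config: read_length must be positive", call. = FALSE)
  rates <- c(cfg$n_inject_rate, cfg$lowq_rate, cfg$multi_hit_rate)
  if (any(rates < 0) || any(rates > 1))
    stop("invalid config: injection rates must lie in [0,1]", call. = FALSE)
  invisible(cfg)
}

#' Read or write a simulation configuration as YAML
#'
#' @param cfg A `sim_config` object.
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  x <- unclass(cfg)
  x$chrom_lengths <- as.list(x$chrom_lengths)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$chrom_lengths <- unlist(x$chrom_lengths)
  do.call(sim_config, x)
}
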