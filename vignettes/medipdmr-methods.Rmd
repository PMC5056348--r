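---
title: "Methods: seed-and-extend DMR calling for two-group MeDIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-and-extend DMR calling for two-group MeDIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
```

## The measurement model

MeDIP-seq enriches methylated DNA by immunoprecipitation before
sequencing, so the number of fragments covering a CpG site is an
(enrichment-weighted) proxy for that site's methylation level.  The
package's unit of analysis is therefore the **per-CpG fragment depth**: a
sites × samples matrix with two group labels, built by counting, for each
sample, the aligned fragments whose 0-based half-open interval overlaps
the 2-bp dinucleotide `[pos, pos+2)`.  Both strands report on the same
site (CpG methylation is symmetric), so fragments are counted without
regard to strand.  All internal coordinates are 0-based half-open; files
on disk follow BED conventions.

Three cleaning steps precede any testing:

* **Read QC** — a read is discarded iff it contains more than 5 `N`
  bases or more than 50% of its bases fall below Phred 5 (both strict
  comparisons, offset-33 encoding).
* **Multi-hit collapsing** — a read aligned to several genomic locations
  is treated as one read; the record first in (chrom, start, end) order
  is kept.  No tie rule beyond coordinate order is imposed.
* **Coverage filter** — a site is retained iff its group-mean raw depth
  is at least 10 in *both* groups.  The published threshold ("less than a
  10 read depth") does not say per-sample, per-group or pooled; the
  group-mean reading keeps power at n = 3 while honouring the threshold,
  and a stricter per-sample-minimum mode ships behind
  `filter_low_coverage(mode = "per-sample")`.

Normalization rescales each sample to its group's mean library size
(library size = post-collapse aligned fragment count):
`factor_s = mean(lib in group)/lib_s`.  Within-sample depth ratios are
preserved exactly; rescaling a single sample's depths is absorbed up to
the common factor its new library contributes to the group mean.

## Site tests and the Bartlett gate

At every retained site the two groups of normalized depths are compared
two-sidedly.  A two-group **Bartlett test** (statistic against
chi-square(1)) routes the comparison: gate passed (p > 0.05) → a
**pooled-variance two-sample t-test** (equal variances justified by the
gate); gate failed → an **exact Mann–Whitney U test** by full enumeration
of the `choose(n1+n2, n1)` group assignments on mid-ranks (normal
approximation with tie correction beyond 5,000 assignments).  Note that
Bartlett's test checks only variance equality, not normality, although it
is conventionally described as a normality-and-homoscedasticity gate; we
implement it as the routing gate it operationally is.

Degenerate inputs are defined explicitly: both groups at zero variance →
Bartlett p = 1 (perfect homoscedasticity); all values identical → test
p = 1; zero pooled variance with unequal means → p = 0.  Site p-values
are floored at 1e-300 before entering log-scale region statistics.

**A structural caveat at n = 3 vs 3**: the exact two-sided Mann–Whitney p
cannot fall below 2/20 = 0.1, so a site routed nonparametrically can
never reach the 0.01 seed threshold.  `call_dmrs()` warns when this
starvation occurs.  How the original analysis handled this is not
recoverable; we implement the procedure as stated.

## Seed-and-extend region detection

Sites with p < 0.01 are **seed CpGs**.  From a seed, the region absorbs
the next downstream CpG while that CpG is itself significant and lies
within 200 bp (`join_window_bp`) of the current region edge; a
non-significant CpG — permitted as a terminator within 2 kb
(`max_gap_bp`) — or a larger gap ends the region.  Candidates grown from
different seeds that overlap are merged, so each reported candidate is a
*maximal run of consecutive significant CpGs with successive gaps ≤ 200
bp*, and a candidate requires at least **five** significant CpGs.  The
test suite checks this reduction against a brute-force maximal-run
enumerator on randomized chains.  Because any non-significant or distant
next CpG terminates extension either way, `max_gap_bp` does not alter the
called set; the parameter is kept for completeness of the published rule.
Extension is specified 3′-downstream only; left-flanking significant CpGs
are captured through their own seeds and the merge step.

## Permutation null and FDR control

Candidate significance uses the **region statistic** `sum(-log10 p)` over
member CpGs — additive, and sensitive to both the number and the strength
of significant sites (the statistic itself is not prescribed by the
published description; this choice is ours).  The null is built by
re-running the site tests and the extension on permuted data: each of
1,000 draws picks one of the distinct *non-identity* balanced group
relabelings (9 exist at 3 vs 3 after complement deduplication, since a
labeling and its complement give identical two-sided p-vectors) and a
uniform circular shift of the site-to-depth assignment, and contributes
the **maximum** candidate statistic of that draw (0 when no candidate
forms).  Empirical region p = (1 + #{null ≥ observed})/(1,001), followed
by Benjamini–Hochberg step-up across candidates; regions with q < 0.01
are reported, with direction "hyper" when group 1's mean normalized depth
over member CpGs exceeds group 2's ("group 1" = first group label in
factor-level order, so a pure label swap exactly flips directions and
changes nothing else — a tested invariant).

Two scheme details matter.  The identity labeling is excluded from null
draws *even when combined with a shift*: a circular shift preserves runs
of significant sites, so identity + shift would carry planted signal into
the null and destroy power.  And with only 9 distinct relabelings the
shifts provide the additional randomization that makes 1,000 draws
non-redundant.  Because each null draw takes a per-draw **maximum**, the
empirical p is conservative (family-wise flavoured), which is the main
reason the caller is clean under the null (no false regions in 20/20
seeded null runs at the defaults).

## The synthetic-data generator

The generator emulates the study design: two groups × 3 replicates,
~50,000 CpG sites on a small multi-chromosome genome, expected depth 30
per CpG, negative-binomial noise (variance `mu + a·mu²`, default
a = 0.2), and 50 planted 10-CpG DMRs at a 3-fold depth ratio (half hyper-,
half hypomethylated in group 1; planted runs are CpG-dense, internal gaps
≤ 200 bp, and separated so neighbouring truth regions cannot merge).  CpG
sites are placed per window with expectation
`width · CpG_o/e · (GC/2)²`, making density increase monotonically with
GC at fixed CpG_o/e; shorter chromosomes get a higher GC baseline, as in
mammalian genomes.  Two optional realism knobs are off by default so that
the depth contract stays exact (group-2 mean = baseline everywhere):

* `density_link` scales a site's mean by (local CpG density / genome
  mean)^g, mimicking MeDIP's preference for CpG-dense fragments; with it,
  window tracks correlate positively with GC and negatively with
  chromosome length.
* `site_sd` multiplies every site's mean by a shared lognormal factor,
  emulating site-to-site methylation heterogeneity.  Without it the
  no-effect group has a *flat* expected profile and replicate samples
  cannot correlate along the genome; sample-clustering behaviour is
  therefore demonstrated (and tested) at `site_sd = 0.8`, where
  within-group correlations exceed between-group ones in ≥ 90% of 20
  seeded runs at effect 3.

Read emission realizes each depth cell as that many fragments.  In the
default `exact_cover` mode fragments are clipped between neighbouring
CpGs so depth counting is an exact inverse (a tested round trip);
`exact_cover = FALSE` instead draws sonication lengths of 100–500 bp, in
which case fragments span neighbouring sites and the round trip is only
approximate.  Configured fractions of reads violate each QC rule, and a
configured fraction of fragments receives decoy alignments (multi-hit
duplicates) at random coordinates.  The dispersion default is our choice
— the depth distribution of the original libraries is not published — and
is exposed in the config.

## Power at the study conditions, honestly

With three replicates per group, seeding at p < 0.01, and NB dispersion
0.2, the per-site probability that a CpG inside a 3-fold planted region
both passes the Bartlett gate and reaches t-test p < 0.01 is ≈ 0.16; five
*consecutive* such sites inside a 10-CpG region occur with probability
≈ 6×10⁻⁴.  Measured over 20 seeded full-scale simulations, recall at
q < 0.01 is 0.00 — candidate regions essentially never form — while the
empirical FDR is 0 and 20/20 null runs produce no calls.  This is a
property of the published procedure at these noise levels, not of the
implementation: at dispersion 0.02 the same caller recovers planted
regions with perfect direction assignment and zero false calls (the
analysis drivers show both regimes side by side).  Consequently, passing
tests here demonstrate correctness and calibration of the procedure; they
do not imply that n = 3 MeDIP-seq at this overdispersion has power to
detect 3-fold regional differences.

## Downstream summaries

**Annotation.**  Five canonical features are built from gene models:
promoter = 2 kb upstream of the TSS (strand-aware; the published analysis
uses 2 kb flanks throughout, and no explicit promoter length, so 2 kb
mirrors that convention), exons, introns (gene span minus exons),
downstream 2 kb past the TES, intergenic = everything else.  A DMR takes
the highest-precedence feature it overlaps by ≥ 1 bp
(promoter > exon > intron > downstream > intergenic; promoter-first
because promoter DMRs drive the downstream biology).  Count tables count
*genes* once per (feature, direction) — a DMR touching two genes' features
counts for both — while the intergenic column counts DMRs.

**Profiles.**  Window tracks default to non-overlapping windows (the
published "sliding window" step is unstated; an overlapping mode is
available), reporting the mean of member-CpG normalized depths — empty
windows are missing, not zero.  Chromosome-level correlations use one
point per chromosome (Pearson r, two-sided p via the t transform);
per-window mode is available.  The gene metaprofile is strand-aware:
2 kb upstream flank in 100-bp bins, gene body rescaled to 40 bins, 2 kb
downstream flank; genes shorter than the bin count are skipped with a
warning.  Sample clustering uses average linkage on 1 − Pearson r over
CpGs inside DMRs; linkage and distance are unstated in the source and
chosen to match common MeDIP practice.

**Validation computations.**  Bisulfite-clone summaries report per-site
percent methylation over the sequenced subclones (ten per region in the
emulated design) and a text lollipop rendering.  2^−ΔΔCt aggregates
multiple reference genes as the arithmetic mean of their Ct (equivalent
to a geometric mean of reference quantities; the aggregation is not
stated in the source), so the calibrator group's geometric-mean
expression is exactly 1.  Fatty-acid summaries class species into
SFA/MUFA/PUFA, compute the PUFA:SFA ratio on group-mean class sums
(rounded to two decimals), and compare classes with Student's t —
unpaired by default, since the compared animals are unrelated, with a
paired option.  Mean adipocyte volume is the count-weighted sphere
volume `V = Σ fi·(π/6)·Di³ / Σ fi`; the source prints its formula only as
an unreadable figure, and this is the standard reading of a
diameter-histogram mean volume.  A body-density formula based on
anthropometric measurements is likewise unrecoverable from the text and
is deliberately not implemented.

## Problem sizes and numerical choices

The test suite and the acceptance script use: full-scale recovery runs of
~50,000 CpGs × 6 samples with 1,000 permutations, 20 seeds each for the
planted and null configurations; oracle-equivalence sweeps of 1,000
random p-vectors (BH), 300 randomized extension chains of ≤ 30 CpGs, and
10,000 fragments against a quadratic overlap counter.  These sizes make a
full run of everything take a few minutes on one CPU.  Determinism: every
generator and the permutation scheme run under an explicit seed with the
caller's RNG state restored afterwards; two runs with the same seed are
byte-identical.  Ties in the Mann–Whitney enumeration use mid-ranks;
comparisons against null statistics use an absolute slack of 1e-12 to
keep ranking stable under floating-point evaluation-order differences.

## Known limitations

* The generator plants rectangular, CpG-dense regions with a single
  effect size per region; real DMRs have ragged boundaries and graded
  effects, and MeDIP efficiency varies with local CpG density in ways the
  optional `density_link` only caricatures.  Passing recovery tests shows
  calibration of the procedure on its own assumptions, not performance on
  real libraries.
* CpG_o/e varies only window-locally in the synthetic genome, so
  chromosome-level correlations with CpG_o/e are weak by construction
  even when GC and length correlations reproduce qualitatively.
* The nonparametric route is starved at n = 3 vs 3 (minimum exact p =
  0.1 > 0.01); sites failing the Bartlett gate cannot seed regions.
* The permutation null's per-draw maximum makes region p-values
  conservative; with candidate-poor data the BH correction then operates
  on very few, coarse-grained empirical p-values (resolution 1/1,001).
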