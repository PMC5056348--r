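# Reported counts of differentially methylated genes per canonical gene
# feature and direction (hyper/hypo in Landrace backfat relative to
# Rongchang backfat); the intergenic column counts DMRs.
feature	hyper	hypo
promoter	406	77
exon	223	78
intron	4489	809
downstream	322	58
intergenic	7962	1338
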