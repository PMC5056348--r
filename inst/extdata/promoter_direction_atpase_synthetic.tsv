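# Promoter methylation direction of the 11 genes enriched in ATPase
# activity (10 of 11 hypermethylated in Landrace backfat).  SYNTHETIC
# COMPLETION: the 11 gene identities and the 10/11 hyper count are
# reported; which single promoter is hypomethylated is not, so it is
# assigned to one gene arbitrarily.
gene	direction
ATP1B2	hyper
ATP5E	hyper
ATP5G1	hyper
ABCA5	hyper
ABCB4	hyper
CHD6	hyper
NSDHL	hyper
DDX6	hyper
DNAL4	hyper
WRN	hyper
RECQL	hypo
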