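# Promoter methylation direction of the 16 genes enriched in lipid
# transport and localization (15 of 16 hypermethylated in Landrace
# backfat).  SYNTHETIC COMPLETION: the five named genes and the 15/16
# hyper count are reported; the remaining gene identities are
# placeholders, with the single hypomethylated promoter assigned to one of
# them arbitrarily.
gene	direction
PLIN1	hyper
BDKRB2	hyper
NSDHL	hyper
APOL1	hyper
APOL4	hyper
lipid_gene06	hyper
lipid_gene07	hyper
lipid_gene08	hyper
lipid_gene09	hyper
lipid_gene10	hyper
lipid_gene11	hyper
lipid_gene12	hyper
lipid_gene13	hyper
lipid_gene14	hyper
lipid_gene15	hyper
lipid_gene16	hypo
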