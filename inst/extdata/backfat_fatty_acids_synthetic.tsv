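# Backfat fatty-acid composition (percent of total fatty acids), one row
# per species, group means for Landrace (LBF) and Rongchang (RBF) backfat.
# SYNTHETIC COMPLETION of a reported composition: the species values for
# C16:0, C18:0, C18:2n-6 and C20:3n-3 and the class totals
# (LBF: SFA 37.39 / PUFA 19.07; RBF: SFA 48.42 / PUFA 9.43) are reported
# measurements; the remaining species (C14:0, C20:4n-6, C18:1) are filled
# in so that each class sums exactly to its reported total and each sample
# sums to 100.
sample	group	species	pct
LBF_mean	LBF	C16:0	22.31
LBF_mean	LBF	C18:0	13.30
LBF_mean	LBF	C14:0	1.78
LBF_mean	LBF	C18:2n-6	16.04
LBF_mean	LBF	C20:3n-3	1.37
LBF_mean	LBF	C20:4n-6	1.66
LBF_mean	LBF	C18:1	43.54
RBF_mean	RBF	C16:0	28.11
RBF_mean	RBF	C18:0	18.26
RBF_mean	RBF	C14:0	2.05
RBF_mean	RBF	C18:2n-6	6.79
RBF_mean	RBF	C20:3n-3	0.81
RBF_mean	RBF	C20:4n-6	1.83
RBF_mean	RBF	C18:1	42.15
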