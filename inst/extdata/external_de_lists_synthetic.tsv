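gene_symbol	direction	dataset_id
ANXA3	up_in_old	GSE5847
PROM1	up_in_old	GSE5847
WIF1	up_in_old	GSE5847
VIM	up_in_old	GSE5847
COL1A1	up_in_old	GSE5847
RARRES3	up_in_young	GSE5847
SCUBE2	up_in_young	GSE5847
ACTB	up_in_young	GSE5847
EPCAM	ns	GSE5847
SPP1	ns	GSE5847
IL8	ns	GSE5847
VEGFA	ns	GSE5847
MMP3	ns	GSE5847
OGN	ns	GSE5847
SFRP2	ns	GSE5847
CCL5	ns	GSE5847
STAT1	ns	GSE5847
IGF1	ns	GSE5847
TGFB2	ns	GSE5847
PDGFB	ns	GSE5847
FGF13	up_in_old	GSE4823
TUBB2B	up_in_old	GSE4823
ANXA3	up_in_old	GSE4823
FN1	up_in_old	GSE4823
SFRP4	up_in_young	GSE4823
COMP	up_in_young	GSE4823
NAT1	up_in_young	GSE4823
GAPDH	up_in_young	GSE4823
SPP1	ns	GSE4823
EPCAM	ns	GSE4823
LPL	ns	GSE4823
SDC4	ns	GSE4823
WISP2	ns	GSE4823
FBLN5	ns	GSE4823
MX1	ns	GSE4823
KRT19	ns	GSE4823
ESR1	ns	GSE4823
WIF1	up_in_old	GSE14548
PROM1	up_in_old	GSE14548
TGFB1	up_in_old	GSE14548
RARRES3	up_in_young	GSE14548
NAT1	up_in_young	GSE14548
COMP	up_in_young	GSE14548
SPP1	ns	GSE14548
ADM	ns	GSE14548
STC1	ns	GSE14548
OMD	ns	GSE14548
MATN3	ns	GSE14548
SERPINE1	ns	GSE14548
PGR	ns	GSE14548
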