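symbol,hgnc_id
EGFR,HGNC:3236
TP53,HGNC:11998
KRAS,HGNC:6407
BRAF,HGNC:1097
PIK3CA,HGNC:8975
PTEN,HGNC:9588
APC,HGNC:583
ALK,HGNC:427
BRCA1,HGNC:1100
BRCA2,HGNC:1101
NRAS,HGNC:7989
HRAS,HGNC:5173
MET,HGNC:7029
RET,HGNC:9967
KIT,HGNC:6342
PDGFRA,HGNC:8803
ERBB2,HGNC:3430
ERBB3,HGNC:3431
FGFR1,HGNC:3688
FGFR2,HGNC:3689
FGFR3,HGNC:3690
IDH1,HGNC:5382
IDH2,HGNC:5383
ATM,HGNC:795
RB1,HGNC:9884
VHL,HGNC:12687
MLH1,HGNC:7127
MSH2,HGNC:7325
MSH6,HGNC:7329
PMS2,HGNC:9122
SMAD4,HGNC:6770
STK11,HGNC:11389
NF1,HGNC:7765
NF2,HGNC:7773
CDKN2A,HGNC:1787
CDH1,HGNC:1748
CTNNB1,HGNC:2514
NOTCH1,HGNC:7881
JAK2,HGNC:6192
FLT3,HGNC:3765
NPM1,HGNC:7910
DNMT3A,HGNC:2978
TET2,HGNC:25941
ASXL1,HGNC:18318
EZH2,HGNC:3527
KMT2D,HGNC:7133
ARID1A,HGNC:11110
SMARCA4,HGNC:11100
SMARCB1,HGNC:11103
AKT1,HGNC:391
MTOR,HGNC:3942
TSC1,HGNC:12362
TSC2,HGNC:12363
ESR1,HGNC:3467
AR,HGNC:644
GNAS,HGNC:4392
GNAQ,HGNC:4390
GNA11,HGNC:4379
SF3B1,HGNC:10768
ROS1,HGNC:10261
NTRK1,HGNC:8031
MYC,HGNC:7553
CCND1,HGNC:1582
MDM2,HGNC:6973
MAP2K1,HGNC:6840
POLE,HGNC:9177
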