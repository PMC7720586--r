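# Cancer-related gene symbols used for recurrence tabulation
KMT2C
KMT2D
KDM6A
ARID1A
TP53
PIK3CA
RB1
EP300
FGFR3
ASXL1
TET1
SETBP1
STAG2
CREBBP
ERBB2
ERCC2
TSC1
CDKN1A
RXRA
ELF3
KRAS
BRAF
HRAS
NFE2L2
FBXW7
ATM
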