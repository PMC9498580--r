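# tga_associated gene panel
KDM6A
FOXH1
GDF1
KMT2D
MEGF8
DNAI1
DISC1
CCDC65
SLC4A1
CLASP1
PLB1
NODAL
ACVR2B
DAND5
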