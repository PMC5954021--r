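gene	arm
VIM	mesenchymal
FN1	mesenchymal
CDH2	mesenchymal
ZEB1	mesenchymal
ZEB2	mesenchymal
SNAI1	mesenchymal
SNAI2	mesenchymal
TWIST1	mesenchymal
TWIST2	mesenchymal
FOXC2	mesenchymal
GSC	mesenchymal
MMP2	mesenchymal
MMP3	mesenchymal
MMP9	mesenchymal
SPARC	mesenchymal
TNC	mesenchymal
COL1A1	mesenchymal
COL3A1	mesenchymal
THBS1	mesenchymal
WNT5A	mesenchymal
CDH1	epithelial
DSP	epithelial
OCLN	epithelial
CLDN3	epithelial
CLDN4	epithelial
CLDN7	epithelial
KRT8	epithelial
KRT18	epithelial
KRT19	epithelial
EPCAM	epithelial
ESRP1	epithelial
ESRP2	epithelial
GRHL2	epithelial
MUC1	epithelial
TJP1	epithelial
CRB3	epithelial
DSG3	epithelial
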