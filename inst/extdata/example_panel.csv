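metal,antigen,pattern,standardized_name
89Y,CD45,CD45(?!RA|RO),CD45
142Nd,CD19,CD19,CD19
145Nd,CD4,CD4(?!5),CD4
146Nd,CD8,CD8a?,CD8
147Sm,CD3,CD3[e]?,CD3
148Nd,CD16,CD16,CD16
160Gd,CD14,CD14,CD14
166Er,CD127,CD127|IL-?7Ra?,CD127
170Er,PD1,PD-?1|CD279,PD1
174Yb,HLADR,HLA-?DR,HLADR
150Nd,pSTAT5,p-?STAT5,pSTAT5
152Sm,pCREB,p-?CREB,pCREB
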