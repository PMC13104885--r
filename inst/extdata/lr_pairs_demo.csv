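ligand,receptor,pathway
vn,Egfr,EGFR
spi,Egfr,EGFR
pyr,htl,FGFR
bnl,htl,FGFR
AstA,AstA-R1,AstA
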