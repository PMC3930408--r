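gene_id	direction
ELF1	up
FHL1	up
GAS1	up
IFI16	up
IGFBP5	up
KDSR	up
KIF3C	up
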