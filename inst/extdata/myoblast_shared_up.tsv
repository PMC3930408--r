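gene_id	direction
ANXA1	up
GATM	up
METAP2	up
PIM2	up
PTPN13	up
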