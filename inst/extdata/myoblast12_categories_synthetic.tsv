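# SYNTHETIC stand-in category-specificity map for the 12 myoblast
# up-regulated classifier genes. The true per-gene assignments come from a
# figure that is not machine-readable; only the per-category totals
# (EWS 5, RMS 2, NB 2, BL 3) are known, and this file reproduces those
# totals with an arbitrary gene-to-category assignment. Signs and ranks
# are placeholders. Use only to exercise count_category_hits.
gene	category	sign	rank	specific_category
ANXA1	EWS	1	1	EWS
GATM	EWS	1	2	EWS
METAP2	EWS	1	3	EWS
PIM2	EWS	1	4	EWS
PTPN13	EWS	1	5	EWS
ELF1	RMS	1	1	RMS
FHL1	RMS	1	2	RMS
GAS1	NB	1	1	NB
IFI16	NB	1	2	NB
IGFBP5	BL	1	1	BL
KDSR	BL	1	2	BL
KIF3C	BL	1	3	BL
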