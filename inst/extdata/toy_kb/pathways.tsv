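gene	pathway
BRAF	MAPK signaling
NRAS	MAPK signaling
KRAS	MAPK signaling
KIT	Receptor tyrosine kinase signaling
ALK	Receptor tyrosine kinase signaling
MET	Receptor tyrosine kinase signaling
EGFR	Receptor tyrosine kinase signaling
FGFR4	FGFR signaling
LYN	Src family kinase signaling
TP53	Genome integrity / DNA damage response
GNA11	G-protein signaling
GNAQ	G-protein signaling
CDKN2A	Cell cycle regulation
MUTATIONAL_BURDEN	Immune response biomarker
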