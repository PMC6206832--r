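gene	drug	variant_scope	specific_variant	effect_direction	databases	evidence_stage	references
BRAF	dabrafenib	specific_variant	V600E	sensitizing	DGIdb,MyCancerGenome,CIViC,OncoKB	approved_same_indication_possible	PMID:22608338
BRAF	LTT462	any_alteration		sensitizing	DGIdb	preclinical	NCT02711345
GNA11	sorafenib	specific_variant	Q209L	sensitizing	DGIdb	smaller_study	PMID:21083380
KIT	sorafenib	any_alteration		sensitizing	DGIdb,MyCancerGenome	smaller_study	PMID:18488160
TP53	carboplatin	specific_variant	V173L	resistance	COSMIC	smaller_study	PMID:21941004
ALK	crizotinib	specific_variant	G1202R	resistance	COSMIC,MyCancerGenome	smaller_study	PMID:27432227
MUTATIONAL_BURDEN	ipilimumab	specific_variant	high	sensitizing	MyCancerGenome	phase3	PMID:25409260
MUTATIONAL_BURDEN	ipilimumab	specific_variant	low	resistance	MyCancerGenome	phase3	PMID:25409260
LYN	bosutinib	amplification		sensitizing	DGIdb	preclinical	PMID:22089421
FGFR4	ponatinib	overexpression		sensitizing	DGIdb	smaller_study	PMID:23139194
MET	crizotinib	overexpression		sensitizing	DGIdb,MyCancerGenome	smaller_study	PMID:26637283
MET	crizotinib	amplification		sensitizing	DGIdb,MyCancerGenome	smaller_study	PMID:26637283
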