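gene	protein_change	known_effect	functional_impact	databases	identifiers
BRAF	V600E	gain_of_function	damaging	COSMIC,ClinVar	COSM476,VCV000013961
TP53	V173L	loss_of_function	damaging	COSMIC	COSM10717
ALK	G1202R	gain_of_function	damaging	COSMIC	COSM5677632
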