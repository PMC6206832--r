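trial_id	title	phase	drugs	location_class	requires_variant	required_variant_key	status
NCT-LTT462-CH	ERK1/2 inhibitor LTT462 in advanced solid tumors	1	LTT462	switzerland	FALSE		recruiting
NCT-DABRA-V600E	Dabrafenib combination in BRAF V600E tumors	2	dabrafenib	switzerland	TRUE	BRAF V600E	recruiting
NCT-IPI-3	Checkpoint blockade in high-burden melanoma	3	ipilimumab	other	FALSE		recruiting
NCT-PONA-2	Pan-FGFR inhibition in FGFR-aberrant cancers	2	ponatinib	neighboring	FALSE		recruiting
NCT-CRIZ-CLOSED	Crizotinib in MET-driven tumors	2	crizotinib	other	FALSE		other
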