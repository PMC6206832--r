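cancer_type	rank	gene
melanoma	1	BRAF
melanoma	2	NRAS
melanoma	3	KIT
uveal melanoma	1	GNA11
uveal melanoma	2	GNAQ
lung adenocarcinoma	1	EGFR
lung adenocarcinoma	2	ALK
lung adenocarcinoma	3	KRAS
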