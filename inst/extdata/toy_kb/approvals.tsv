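drug	approved_indications	swissmedic_approved
dabrafenib	melanoma	TRUE
LTT462		FALSE
sorafenib	renal cell carcinoma;hepatocellular carcinoma	TRUE
carboplatin	ovarian carcinoma;lung adenocarcinoma	TRUE
crizotinib	lung adenocarcinoma	TRUE
ipilimumab	melanoma	TRUE
bosutinib	chronic myeloid leukemia	TRUE
ponatinib	chronic myeloid leukemia	TRUE
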