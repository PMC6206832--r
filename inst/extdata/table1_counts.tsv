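patient_id	cohort	cancer_type	n_actionable	n_therapies_total	n_cancer_type_specific	n_off_label	n_investigational	n_lacking_benefit
1	comprehensive	cutaneous melanoma	13	12	2	4	6	NA
2	comprehensive	cutaneous melanoma	13	19	2	12	5	5
3	comprehensive	cutaneous melanoma	6	12	3	4	5	5
4	comprehensive	uveal melanoma	3	7	0	4	3	5
5	comprehensive	cutaneous melanoma	5	8	2	5	1	3
6	comprehensive	mucosal melanoma	3	7	0	4	3	3
7	comprehensive	mucosal melanoma	6	12	0	7	5	1
8	comprehensive	uveal melanoma	4	10	0	4	6	1
9	comprehensive	uveal melanoma	4	10	0	4	6	1
10	comprehensive	uveal melanoma	5	11	0	5	6	1
11	comprehensive	cutaneous melanoma	4	6	0	4	2	0
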