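patient_id	cohort	cancer_type	n_actionable	n_therapies_total	n_cancer_type_specific	n_off_label	n_investigational	n_lacking_benefit
12	panel	fibroblastic osteosarcoma	0	0	0	0	0	0
13	panel	head and neck squamous cell carcinoma	12	12	6	6	0	0
14	panel	lung neuroendocrine carcinoma	1	1	0	1	0	0
15	panel	ovarian serous carcinoma	1	1	1	0	0	1
16	panel	cutaneous melanoma	2	3	2	1	0	0
17	panel	chondrosarcoma	10	9	0	9	0	3
18	panel	lung adenocarcinoma	0	0	0	0	0	0
19	panel	lung adenocarcinoma	1	0	0	0	0	1
20	panel	lung squamous cell carcinoma	1	1	1	0	0	1
21	panel	neuroectodermal sarcoma	0	0	0	0	0	0
22	panel	cutaneous melanoma	5	11	1	9	1	1
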