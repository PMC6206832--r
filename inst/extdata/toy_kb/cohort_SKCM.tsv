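gene	value1	value2	value3	value4	value5	value6	value7	value8	value9	value10	value11	value12
BRAF	42.1	55.3	61.0	48.2	39.5	58.7	44.9	52.4	60.2	46.8	41.3	57.5
MET	30.4	45.2	50.1	38.6	28.9	47.3	33.5	42.8	49.0	36.1	31.2	46.6
LYN	20.5	35.8	40.2	28.1	19.4	37.6	23.9	32.7	39.5	26.3	21.8	36.9
FGFR4	10.2	25.6	30.3	18.4	9.8	27.1	13.7	22.9	29.6	16.5	11.4	26.8
KIT	50.7	65.1	70.4	58.3	49.2	67.8	53.6	62.5	69.1	56.9	51.8	66.2
NRAS	60.3	75.9	80.6	68.7	59.1	77.4	63.8	72.6	79.3	66.4	61.7	76.1
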