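group	pct_detected	mean_gc	mean_len	pct_drosophilid	pct_human	pct_rnai	pct_lower_viability	n
mutant	62	0.54	80.9	75	68	50	100	47
fully_viable	55	0.53	76.8	65	48	35	0	29
all_scds	55.4	0.51	72.8	47.5	34.5	27.5	62	862
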