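sample_id	group	lesion	site	mutational_load	tmb	exonic_ms_indels	msi_score	combined_sig6_15
31001	MMR-proficient	Adenoma	R cheek	184	2.7	13	0.34	NA
44001	MMR-proficient	Adenoma	L temple	80	1.2	11	0.02	NA
67001	MMR-proficient	Adenoma	L neck	100	1.5	15	0.24	NA
10101	MMR-deficient	Adenoma	R nasal tip	943	14.0	139	2.54	39
00011	MMR-deficient	Carcinoma	Thigh	1341	19.9	555	21.11	50
04001	MMR-deficient	Carcinoma	Back	2421	36.0	674	23.53	34
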