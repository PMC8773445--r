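chrom	pos_bp	rate_cM_per_Mb	map_cM
21	26000000	1.31	45
21	26200000	1.31	45.262
21	26400000	1.31	45.524
21	26600000	1.31	45.786
21	26800000	1.31	46.048
21	27000000	1.31	46.31
21	27200000	1.31	46.572
21	27400000	1.31	46.834
21	27600000	1.31	47.096
21	27800000	1.31	47.358
21	28000000	1.31	47.62
21	28200000	1.31	47.882
21	28400000	1.31	48.144
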