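dataset	n_species	n_samples	n_columns	variable_sites	variable_pct	diagnostic_sites	diagnostic_pct	min_rate	max_rate	mean_intra	intra_min	intra_max	mean_inter	inter_min	inter_max	nj_species	blast_species
option1	23	52	1704	95	5.6	24	1.4	0	3.1	0.3	0	1.4	0.5	0	3.1	1	NA
option2	23	52	1909	231	12.1	72	3.8	0	8.4	1.1	0	4.1	1.9	0	8.8	2	NA
matK	23	52	721	61	8.5	19	2.6	0	3.8	0.5	0	2.7	0.8	0	3.5	2	NA
trnH-psbA	56	226	698	203	29.1	107	15.3	0	12.5	1.0	0	8.8	2.0	0	13.0	8	9
rpl32-trnL	56	202	1023	451	44.1	193	18.9	0	16.5	1.2	0	15.5	1.9	0	16.0	3	NA
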