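# Published per-chromosome mean CpG methylation percentages (WGBS) for the
# HEK-CT control line and the two HEK-BAHD1 overexpression replicates.
chrom	control	treatment_rep1	treatment_rep2	x_like
chr1	70.09	72.06	72.47	FALSE
chr2	67.45	69.2	70.32	FALSE
chr3	67.34	69.01	69.75	FALSE
chr4	59.67	61.31	61.68	FALSE
chr5	61.81	61.66	61.48	FALSE
chr6	68.21	70.46	71.4	FALSE
chr7	67.21	69.13	70.23	FALSE
chr8	60.9	63.21	63.85	FALSE
chr9	71.45	73.1	74.42	FALSE
chr10	65.97	67.84	67.33	FALSE
chr11	66.45	68.06	68.92	FALSE
chr12	66.03	68	68.88	FALSE
chr13	63.38	65.22	65.63	FALSE
chr14	67.08	68.29	69.75	FALSE
chr15	71.58	73.15	74.24	FALSE
chr16	57.3	57.39	60.03	FALSE
chr17	75.16	76.47	77.8	FALSE
chr18	63.89	65.24	66.41	FALSE
chr19	70.6	71.93	73.17	FALSE
chr20	71.71	73.71	75.27	FALSE
chr21	63.06	67.94	67.97	FALSE
chr22	76.1	77.47	79.45	FALSE
chrX	42.91	38.97	38.9	TRUE
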