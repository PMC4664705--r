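# Published per-chromosome counts of BAHD1-specific DMRs (300 bp windows,
# Fisher/BH q < 0.1, >= 25% reproducible methylation difference) with
# chromosome lengths.
chrom	total	hyper	hypo	length_bp	x_like
chrX	7508	1368	6140	1.55e8	TRUE
chr6	6447	5871	576	1.71e8	FALSE
chr5	6587	5877	710	1.81e8	FALSE
chr20	2232	2055	177	6.30e7	FALSE
chr1	8676	8128	548	2.49e8	FALSE
chr2	8373	7106	1267	2.43e8	FALSE
chr3	6649	5902	747	1.98e8	FALSE
chr10	4333	3979	354	1.36e8	FALSE
chr12	4263	3988	275	1.34e8	FALSE
chr7	4987	4576	411	1.59e8	FALSE
chr8	4316	3783	533	1.46e8	FALSE
chr17	2288	2014	274	8.12e7	FALSE
chr11	3638	3157	481	1.35e8	FALSE
chr19	1515	1414	101	5.91e7	FALSE
chr4	4845	4287	558	1.91e8	FALSE
chr21	1152	942	210	4.81e7	FALSE
chr9	3259	2907	352	1.41e8	FALSE
chr16	2019	1865	154	9.04e7	FALSE
chr14	2121	1803	318	1.07e8	FALSE
chr18	1514	1301	213	7.81e7	FALSE
chr13	2151	1929	222	1.15e8	FALSE
chr15	1807	1559	248	1.03e8	FALSE
chr22	678	613	65	5.13e7	FALSE
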