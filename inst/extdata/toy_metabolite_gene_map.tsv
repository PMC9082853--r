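trait	gene	gene_chrom	gene_tss
M001	GENEX	chr1	500000
M001	GENEY	chr1	900000
M001	GENEZ	chr2	750000
M002	GENEW	chr3	1200000
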