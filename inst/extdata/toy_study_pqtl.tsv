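ProteinID	SNP_Chr	SNP_Pos	GeneSymbol	Gene_Chr	Gene_TSS	LogP	Signal
P001	chr1	1200000	GENE1	chr1	1150000	45.2	primary
P001	chr7	880000	GENE1	chr1	1150000	12.1	primary
P002	chr2	5000000	GENE2	chr2	5400000	30.0	primary
P002	chr2	5100000	GENE2	chr2	5400000	22.0	secondary
P003	chr3	2000000	GENE3A	chr5	900000	18.0	primary
P004	chr4	7000000	GENE4	chr4	6100000	9.5	primary
P004	chr4	7000000	GENE4B	chr4	8100000	9.5	primary
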