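##fileformat=VCFv4.2
##contig=<ID=1>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4	S5	S6	S7	S8
1	6120	sv00001	A	G	.	PASS	.	GT	0|0	1|1	0|0	1|0	1|0	0|0	1|1	0|0
1	36520	sv00002	A	G	.	PASS	.	GT	1|1	0|0	1|1	0|1	0|1	1|1	0|0	1|1
1	41352	sv00003	A	G	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	51849	sv00004	A	G	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	52922	sv00005	A	G	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1
1	59648	sv00006	A	G	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	66541	sv00007	A	G	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	83869	sv00008	A	G	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	84843	sv00009	A	G	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
1	87015	sv00010	A	G	.	PASS	.	GT	1|1	1|1	1|1	1|1	1|1	1|1	1|1	1|1
1	90000	sv00011	A	G	.	PASS	.	GT	0|0	1|1	0|0	1|0	1|0	0|0	1|1	0|0
1	98634	sv00012	A	G	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
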