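##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
1	1001	.	A	G	60	PASS	.	GT	0/0	0/1	1/1
1	2002	.	C	T	55	PASS	.	GT	0|1	1/0	./.
1	3003	.	G	A	80	PASS	.	GT	1/1	1/1	0/0
1	4004	.	T	C	.	PASS	.	GT	0/0	0/0	0/1
1	5005	.	A	C	90	PASS	.	GT	0/1	0/0	0/0
1	6006	.	A	G,T	70	PASS	.	GT	1/2	0/1	0/0
2	1500	.	C	G	45	PASS	.	GT	0/0	1/1	0/1
X	999	.	A	T	50	PASS	.	GT	0/0	0/0	0/0
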