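##fileformat=VCFv4.2
##source=toy
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	NA00001
chr1	150	.	A	G	.	PASS	.	GT	0/1
chr1	300	.	C	T	.	PASS	.	GT	1/1
chr1	550	.	G	A	.	PASS	.	GT	0|1
chr1	700	.	T	C	.	PASS	.	GT	0/2
chr1	900	.	TA	T	.	PASS	.	GT	0/1
chr2	120	.	C	G	.	PASS	.	GT	0/1
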