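##gff-version 2
##source-version rtracklayer 1.62.0
##date 2026-10-02
chr1	txtile	transcript	1001	2900	.	.	.	gene_id "FL1"; transcript_id "FL1";
chr1	txtile	exon	1001	1400	.	.	.	gene_id "FL1"; transcript_id "FL1";
chr1	txtile	exon	1701	1950	.	.	.	gene_id "FL1"; transcript_id "FL1";
chr1	txtile	exon	2501	2900	.	.	.	gene_id "FL1"; transcript_id "FL1";
chr1	txtile	transcript	8001	8800	.	.	.	gene_id "FL2"; transcript_id "FL2";
chr1	txtile	exon	8001	8600	.	.	.	gene_id "FL2"; transcript_id "FL2";
chr1	txtile	exon	8701	8800	.	.	.	gene_id "FL2"; transcript_id "FL2";
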