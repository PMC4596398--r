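##gff-version 3
chr1	demo	gene	1001	2900	.	+	.	ID=ANN001;Name=known_gene
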