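track name=junctions description="demo junctions"
chr1	1350	1750	JUNC00001	5	+	1350	1750	255,0,0	2	50,50	0,350
chr1	1900	2550	JUNC00002	9	+	1900	2550	255,0,0	2	50,50	0,600
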