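chr1	toy	exon	101	200	.	+	.	gene_id "TOY1"; transcript_id "TOY1_t1";
chr1	toy	exon	501	650	.	+	.	gene_id "TOY1"; transcript_id "TOY1_t1";
chr1	toy	exon	701	800	.	+	.	gene_id "TOY1"; transcript_id "TOY1_t1";
chr1	toy	exon	101	200	.	+	.	gene_id "TOY1"; transcript_id "TOY1_t2";
chr1	toy	exon	301	400	.	+	.	gene_id "TOY1"; transcript_id "TOY1_t2";
chr1	toy	exon	501	650	.	+	.	gene_id "TOY1"; transcript_id "TOY1_t2";
chr1	toy	exon	901	1000	.	+	.	gene_id "TOY1"; transcript_id "TOY1_t2";
chr1	toy	exon	101	200	.	+	.	gene_id "TOY1"; transcript_id "TOY1_t3";
chr1	toy	exon	501	650	.	+	.	gene_id "TOY1"; transcript_id "TOY1_t3";
chr1	toy	exon	901	1000	.	+	.	gene_id "TOY1"; transcript_id "TOY1_t3";
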