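case_id	karyotype_text	sex	clinical_status	shapes	mosaic	clone_counts	inheritance	groups	interval_chrom	interval_start	interval_end	build	modalities	phenotype_terms	arm_class	source_table
10	mos 47,XN,+mar[74%]/46,XN[26%].arr[hg19] 11p12~11.2(42,922,228_50,768,675)x3	unknown	abnormal		TRUE	74%;26%			chr11	42922228	50768675	GRCh37	aCGH		p	table4
13	mos 47,XY,+mar[33%]/46,XY[67%]	male	abnormal	min	TRUE	33%;67%			chr11	40233424	54943424	GRCh37	aCGH		p	table4
E	46,XY,dup(11)(p12p11.2)mat.arr[hg19] 11p12p11.2(40,231,033_50,762,504)x3	male	abnormal		FALSE		maternal		chr11	40231033	50762504	GRCh37	aCGH		p	table4
F	46,XY,ins(11)(11;11)(q14.5p14.1p11.2)	male	abnormal		FALSE				chr11	30000000	51600000	GRCh37	GTG		p	table4
G	mos 46,XY,dup(11)(q11q13.3)[29]/46,XY[6]	male	abnormal		TRUE	29;6			chr11	56243424	79072352	GRCh37	aCGH		q	table4
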