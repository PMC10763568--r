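case_id	karyotype_text	sex	clinical_status	shapes	mosaic	clone_counts	inheritance	groups	interval_chrom	interval_start	interval_end	build	modalities	phenotype_terms	arm_class	source_table
13	mos 47,XY,+mar[33%]/46,XY[67%]	male	abnormal	min	TRUE	33%;67%			chr11	40233424	54943424	GRCh37	banding;ish;aCGH	developmental delay;hypotonia	p	table5
C	46,XX,dup(11)(p11.2p11.1) LSI-FISH duplication size ~6 Mb	female	abnormal		FALSE								banding;ish	developmental delay	p	table5
D	46,XY,dup(11)(p12)	male	abnormal		FALSE								banding	growth retardation;facial dysmorphism;developmental delay;intellectual disability	p	table5
E	46,XY,dup(11)(p12p11.2)mat.arr[hg19] 11p12p11.2(40,231,033_50,762,504)x3	male	abnormal		FALSE		maternal		chr11	40231033	50762504	GRCh37	banding;aCGH	facial dysmorphism;developmental delay	p	table5
F	46,XY,ins(11)(11;11)(q14.5p14.1p11.2)	male	abnormal		FALSE				chr11	30000000	51600000	GRCh37	banding	cleft palate;facial dysmorphism;developmental delay	p	table5
15	mos 47,XX,+mar mat[70%]/46,XX[30%].ish r(11)(::p11.12→q13.1::)(RP11-397M16+,D11Z1+,RP11-77M17+)	female	abnormal	r	TRUE	70%;30%	maternal						banding;ish;aCGH	blepharophimosis/ptosis;strabism;facial dysmorphism;developmental delay;intellectual disability	q	table5
G	mos 46,XY,dup(11)(q11q13.3)[29]/46,XY[6]	male	abnormal		TRUE	29;6			chr11	56243424	79072352	GRCh37	banding;aCGH	facial dysmorphism;heart defect;developmental delay	q	table5
H	mos 46,XY,dup(11)(q12.1q13.3)[53%]/46,XY[47%]	male	abnormal		TRUE	53%;47%							banding	facial dysmorphism;developmental delay	q	table5
29	mos 47,XX,+mar[60%-90%]/46,XX[10%-40%].ish min(11)(:p11.21→q13.1:)(RP11-397M16+,D11Z1+,RP11-77M17+)	female	abnormal	min	TRUE	60%-90%;10%-40%			chr11	49850000	64600000	GRCh37	banding;ish;aCGH	growth retardation;facial dysmorphism;heart defect;developmental delay;hypotonia	q	table5
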