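record_id	classification	chrom	start	end	build	flank_only	synthetic_interval
dgv1111n100	benign	chr11	47675469	52500000	GRCh37	FALSE	TRUE
nsv832175	benign	chr11	54500000	60516539	GRCh37	FALSE	TRUE
DECIPHER-411500	pathogenic	chr11	44048321	45048321	GRCh37	TRUE	TRUE
DECIPHER-300792	pathogenic	chr11	61479322	62479322	GRCh37	TRUE	TRUE
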