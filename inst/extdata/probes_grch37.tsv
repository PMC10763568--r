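probe	chrom	start	end	build	note
D11Z1	chr11	51600000	55700000	GRCh37	centromeric alpha-satellite; operational span equals the acen anchor
RP11-397M16	chr11	48303671	48479496	GRCh37	BAC clone, 11p11.2
RP11-77M17	chr11	57352936	57521103	GRCh37	BAC clone, 11q12
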