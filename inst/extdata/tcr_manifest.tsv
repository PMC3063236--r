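pdb_id	tcr_name	beta_chain	cdr3_seq	y40_author_number
1D9K	D10	B	CASGGQGRAEQFF	NA
1U3H	172.10	E	CASGDAGGGYEQYF	NA
2OI9	2C	E	CASGGGGTLYF	NA
1FYT	HA1.7	E	CASSSTGLPYGYTF	NA
1LP9	AHIII 12.2	E	CASSDWVSYEQYF	NA
1NFD	N15	B	CASSLRWGDEQYF	NA
1OGA	JM22	E	CASSRSSYEQYF	NA
2BNQ	1G4	E	CASSYVGNTGELFF	NA
2ESV	KK50.4	E	CASSQDRDTQYF	NA
1ZGL	3A6	E	CASSLADRVNTEAFF	NA
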