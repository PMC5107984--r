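drug_class	gene	pf_sum
anthracycline	NOTCH2	-21
anthracycline	CAV1	-331
anthracycline	BCL2L11	-238
anthracycline	CXCL9	-8
anthracycline	AKAP7	-2
anthracycline	IRF5	-32
anthracycline	CD244	-1
anthracycline	LAPTM4B	-46
anthracycline	MXRA7	-2
anthracycline	GNA15	-204
anthracycline	RHOBTB3	-1
anthracycline	UBC	-1101
anthracycline	EP300	-308
anthracycline	ELAVL1	-73
anthracycline	HDAC2	-146
anthracycline	HSP90AA1	-756
anthracycline	GRB2	-495
anthracycline	ZAP70	-322
anthracycline	FOXP1	-2
taxane	FOXP1	-48
taxane	NME7	-41
taxane	EPS8	-87
taxane	IL1R1	-9
taxane	DDX17	-7
taxane	CNR1	-2
taxane	UBC	274
taxane	ELAVL1	7
taxane	HMOX1	17
taxane	HCK	50
taxane	TXN	1
taxane	HSP90AA1	138
taxane	NOTCH2	3
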