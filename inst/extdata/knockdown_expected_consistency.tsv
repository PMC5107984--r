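drug_class	gene	category	restricted
anthracycline	NOTCH2	moderate	TRUE
anthracycline	CAV1	strong	TRUE
anthracycline	BCL2L11	strong	TRUE
anthracycline	CXCL9	weak	TRUE
anthracycline	AKAP7	inconsistent	FALSE
anthracycline	IRF5	moderate	FALSE
anthracycline	CD244	weak	FALSE
anthracycline	LAPTM4B	moderate	FALSE
anthracycline	MXRA7	weak	FALSE
anthracycline	GNA15	strong	FALSE
anthracycline	RHOBTB3	weak	FALSE
anthracycline	UBC	strong	FALSE
anthracycline	EP300	inconsistent	FALSE
anthracycline	ELAVL1	moderate	TRUE
anthracycline	HDAC2	inconsistent	FALSE
anthracycline	HSP90AA1	inconsistent	FALSE
anthracycline	GRB2	strong	FALSE
anthracycline	ZAP70	strong	FALSE
anthracycline	FOXP1	weak	FALSE
taxane	FOXP1	inconsistent	FALSE
taxane	NME7	inconsistent	FALSE
taxane	EPS8	inconsistent	FALSE
taxane	IL1R1	inconsistent	FALSE
taxane	DDX17	inconsistent	FALSE
taxane	CNR1	inconsistent	FALSE
taxane	UBC	inconsistent	FALSE
taxane	ELAVL1	weak	FALSE
taxane	HMOX1	moderate	FALSE
taxane	HCK	moderate	FALSE
taxane	TXN	weak	FALSE
taxane	HSP90AA1	strong	FALSE
taxane	NOTCH2	weak	FALSE
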