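ligand	receptor	source
CSF2	CSF2RA	iuphar
CSF2	CSF2RB	iuphar
VEGFA	FLT1	dlrp
VEGFA	KDR	dlrp
TGFB1	TGFBR1	iuphar
TGFB1	TGFBR2	dlrp
IL6	IL6R	iuphar
CCL2	CCR2	dlrp
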