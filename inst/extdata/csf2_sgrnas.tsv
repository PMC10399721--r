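name	target	sequence
sgRNA4	Csf2	CCCTCACTCACCAACGTGAC
sgRNA6	Csf2	GGCTGTAGACCACAATGCCC
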