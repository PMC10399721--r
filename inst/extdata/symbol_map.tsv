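raw	species	canonical
Csf2ra	mouse	CSF2RA
Csfr2a	mouse	CSF2RA
Csf2rb	mouse	CSF2RB
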