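ICAF_SIGNATURE	synthetic inflammatory-CAF program	CXCL8	IL6	CXCL1	CXCL2	IL11	LIF	CCL2	CXCL12
MYCAF_SIGNATURE	synthetic myofibroblastic-CAF program	ACTA2	TAGLN	MYL9	POSTN	MYH11	TPM1	TPM2	CTGF
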