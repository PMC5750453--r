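TARGET	PROXY	R2	R_SIGN
rs200634877	rs166079	0.75	-1
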