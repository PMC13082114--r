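YAL001C	12	27	YAL001C_u1	0	+
YBR020W	30	45	YBR020W_u1	0	+
YBR020W	60	75	YBR020W_u2	0	+
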