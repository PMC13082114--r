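YBR020W	30	45	YBR020W_mpra1	0	+
YGL035C	9	18	YGL035C_mpra1	0	+
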