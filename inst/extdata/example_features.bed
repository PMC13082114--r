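YAL001C	0	72	YAL001C:utr5	0	+
YAL001C	72	3276	YAL001C:morf	0	+
YAL001C	3276	3420	YAL001C:utr3	0	+
YBR020W	0	120	YBR020W:utr5	0	+
YBR020W	120	1803	YBR020W:morf	0	+
YBR020W	1803	1950	YBR020W:utr3	0	+
YGL035C	0	96	YGL035C:utr5	0	+
YGL035C	96	1449	YGL035C:morf	0	+
YGL035C	1449	1600	YGL035C:utr3	0	+
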