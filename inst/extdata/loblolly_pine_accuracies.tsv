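trait	blending	ca	pp
ABA	0.4306	0.4619	0.4467
C5C6	0.1495	0.1435	0.1508
CWAB	0.4244	0.4407	0.4285
TSH	0.3188	0.3398	0.3140
THLC	0.3265	0.3373	0.3350
RN	0.1448	0.1554	0.1261
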