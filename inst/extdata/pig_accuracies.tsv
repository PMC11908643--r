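trait	blending	ca	pp
ADG	0.5280	0.5334	0.5373
BF	0.2026	0.2288	0.2064
BH	0.3557	0.3510	0.3589
LEA	0.1308	0.0900	0.1359
LP	0.2767	0.2752	0.2883
OTW	0.3164	0.3225	0.3080
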