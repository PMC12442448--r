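feature	label	positions
ref_id	synthetic_HaloPETase1_like_typeIII	
triad	ser	156
triad	his	236
triad	asp	206
clamp	anchor1	88
clamp	anchor2	186
oxyanion	pos1	88
oxyanion	pos2	157
subsite1	.	88,163,186
subsite2	.	94,95,96,101
extended_loop	.	243,244,245,246,247,248,249,250,251
loop_window	loop1	85,91
loop_window	loop2	116,120
loop_window	loop3	159,173
disulfide	pair1	64,126
disulfide	pair2	273,276
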