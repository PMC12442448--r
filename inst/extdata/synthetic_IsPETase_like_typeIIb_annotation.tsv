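feature	label	positions
ref_id	synthetic_IsPETase_like_typeIIb	
triad	ser	160
triad	his	237
triad	asp	206
clamp	anchor1	87
clamp	anchor2	185
oxyanion	pos1	87
oxyanion	pos2	161
subsite1	.	87,119,185
subsite2	.	93,94,95,100
extended_loop	.	244,245,246,247,248,249,250,251,252
loop_window	loop1	84,90
loop_window	loop2	115,124
loop_window	loop3	163,172
disulfide	pair1	203,239
disulfide	pair2	273,289
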