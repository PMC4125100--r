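2L	15	A	12:0:5:0:0:0	7:0:9:0:0:0
2L	42	G	0:0:0:17:0:0	3:0:0:14:0:1
2R	8	T	0:11:0:4:1:0	0:9:0:6:0:0
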