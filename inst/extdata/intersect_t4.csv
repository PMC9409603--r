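alternative,e1,e2
d1,0.02:0.2,0:0.08
d2,0.12:0.09,0.4:0.08
d3,0.72:0.06,0.01:0.8
d4,0.49:0.08,0.42:0.09
d5,0:0.08,0:1
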