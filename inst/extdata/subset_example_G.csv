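alternative,e1,e2,e4
d1,0.1:0.4,0:1,0.5:0.2
d2,0.3:0.3,0.5:0.8,0.2:0.5
d3,0.8:0.1,0.1:0.8,0.7:0.1
d4,0.7:0.1,0.6:0.9,0:1
d5,0:1,0:1,0:1
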