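alternative,e1,e2,e3,e5
d1,0.2:0.5,0:0.8,0.6:0.5,0.6:0.3
d2,0.4:0.3,0.8:1,0.2:0.3,0.7:0.6
d3,0.9:0.6,0.1:1,0.8:0.5,0.5:0.8
d4,0.7:0.8,0.7:0.1,0:1,0.8:0.5
d5,0:0.8,0:1,0:0.9,0:0.9
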