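alternative,not e1,not e2,not e3,not e5
d1,0.8:0.5,1:0.2,0.4:0.5,0.4:0.7
d2,0.6:0.7,0.2:0,0.8:0.7,0.3:0.4
d3,0.1:0.5,0.9:0,0.2:0.5,0.5:0.2
d4,0.3:0.2,0.3:0.9,1:0,0.2:0.5
d5,1:0.2,1:0,1:0.1,1:0.1
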