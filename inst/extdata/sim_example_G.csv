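alternative,e1,e2,e3
x1,0.4:0.5,0.6:0.7,0.4:0.9
x2,0.3:0.5,0.5:0.6,0.3:0.6
x3,0.2:0.6,0.2:0.5,0.2:0.6
x4,0.9:0.4,0.1:0.3,0.1:0.5
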