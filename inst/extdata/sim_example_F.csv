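alternative,e1,e2,e3
x1,0.2:0.6,0.1:0.8,0.2:0.4
x2,0.5:0.8,0.2:0.4,0.4:0.8
x3,0.9:0.4,0.6:0.4,0.7:0.6
x4,1:0.6,0.5:0.6,0.9:0.4
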