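alternative,e1,e2,e3,e4,e5,e6,e7,e8
y,0.5:0.5,0.4:0.8,0.8:0.7,0.2:0.8,0.2:0.8,0.5:0.5,0.5:0.5,0.6:0.5
n,0.5:0.8,0.5:0.8,0:1,0.7:0.7,0.6:0.7,0.4:0.5,0.4:0.5,0.2:0.7
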