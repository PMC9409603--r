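alternative,e1,e2,e3,e4,e5,e6,e7,e8
y,0.9:0.9,0.8:0.8,0.1:0.9,0.5:0.9,0.5:0.9,0.8:0.9,0.5:0.9,0.6:0.9
n,0.1:0.9,0.1:0.7,0.8:0.9,0.5:0.9,0.5:0.9,0.1:0.9,0.5:0.9,0.4:0.9
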