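alternative,e1,e2,e3,e4,e5
d1,0.28:0.7,0:1,0.6:0.5,0.5:0.2,0.6:0.3
d2,0.58:0.51,0.9:1,0.2:0.3,0.2:0.5,0.7:0.6
d3,0.98:0.64,0.18:1,0.8:0.5,0.7:0.1,0.5:0.8
d4,0.91:0.82,0.88:0.91,0:1,0:1,0.8:0.5
d5,0:1,0:1,0:0.9,0:1,0:0.9
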