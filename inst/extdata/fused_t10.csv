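alternative,e1,e2,e3,e4,e5,e6,e7,e8
y,0.96:0.97,0.96:0.95,0.95:0.5,0.76:0.97,0.76:0.97,0.75:0.96,0.76:0.95,0.92:0.9
n,0.59:0.98,0.8:0.96,0.44:1,0.92:0.95,0.88:0.95,0.78:0.92,0.82:0.9,0.6:0.94
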