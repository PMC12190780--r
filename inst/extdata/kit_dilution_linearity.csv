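factor,expected,observed,cv
2,1500,1508.6,0.9
4,750,793.75,0.3
8,375,388.05,2.2
16,187.5,182.4,1.5
32,93.8,94.7,1.2
64,46.9,51.95,0.1
128,23.4,23.65,5.7
256,11.7,5.9,28.8
512,5.9,2.7,55.6
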