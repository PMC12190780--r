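sample_id,spike_pg,measured,cv
S1,0,164,2.3
S1,100,261,1.4
S1,200,360,0.6
S2,0,220,1.4
S2,100,319,3.2
S2,200,413,1.2
S3,0,392,2.7
S3,100,483,1.2
S3,200,568,1.0
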