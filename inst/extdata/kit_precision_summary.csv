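assay,level,n,mean,sd,cv_printed
intra,low,20,159,8.5,5.4
intra,medium,20,579,18.6,3.2
intra,high,20,1177,61.7,5.2
inter,low,25,207,17.8,8.6
inter,medium,25,607,31.1,5.1
inter,high,25,1020,81.9,8.0
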