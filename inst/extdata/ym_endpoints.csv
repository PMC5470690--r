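part,day,emean_kpa,sd_kpa
whole,1,2.36,0.41
whole,14,13.24,1.71
head,1,2.01,0.28
head,14,13.29,1.48
body,1,3.27,0.57
body,14,15.91,2.05
tail,1,1.79,0.36
tail,14,10.51,1.61
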