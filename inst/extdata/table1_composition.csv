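day,part,Rr,Rp,Rb
2,head,97.02,2.47,0.51
2,body,95.75,3.54,0.71
2,tail,92.63,6.27,1.10
5,head,81.72,16.49,1.79
5,body,80.22,19.30,0.48
5,tail,77.44,16.38,6.18
11,head,47.39,42.17,10.44
11,body,50.70,34.54,14.76
11,tail,74.20,16.37,9.43
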