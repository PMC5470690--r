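animal,part,Rr,Rp,Rb
33,head,19.65,68.59,11.76
33,body,29.98,46.75,23.27
33,tail,11.59,60.92,27.49
36,head,38.87,55.62,5.51
36,body,33.92,58.41,7.67
36,tail,31.25,58.78,9.97
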