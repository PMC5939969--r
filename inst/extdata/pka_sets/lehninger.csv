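# source: Nelson & Cox, Lehninger Principles of Biochemistry (transcribed)
group,pka
n_term,9.69
c_term,2.34
C,8.33
D,3.86
E,4.25
H,6.00
K,10.53
R,12.48
Y,10.07
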