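# source: Rodwell, J.D. (1982) Anal. Biochem. 119, 440-449 (transcribed)
group,pka
n_term,8.00
c_term,3.10
C,8.33
D,3.68
E,4.25
H,6.00
K,11.50
R,11.50
Y,10.07
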