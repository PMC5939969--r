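# source: Sillero, A., Ribeiro, J.M. (1989) Anal. Biochem. 179, 319-325 (transcribed)
group,pka
n_term,8.20
c_term,3.20
C,9.00
D,4.00
E,4.50
H,6.40
K,10.40
R,12.00
Y,10.00
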