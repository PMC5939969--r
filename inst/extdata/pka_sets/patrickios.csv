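# source: Patrickios, C.S., Yamasaki, E.N. (1995) Anal. Biochem. 231, 82-91 (transcribed; C, H, Y non-ionizable)
group,pka
n_term,11.20
c_term,4.20
D,4.20
E,4.20
K,11.20
R,11.20
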