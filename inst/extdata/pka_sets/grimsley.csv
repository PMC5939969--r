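# source: Grimsley, G.R., Scholtz, J.M., Pace, C.N. (2009) Protein Sci. 18, 247-251 (transcribed)
group,pka
n_term,7.70
c_term,3.30
C,6.80
D,3.50
E,4.20
H,6.60
K,10.50
R,12.04
Y,10.30
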