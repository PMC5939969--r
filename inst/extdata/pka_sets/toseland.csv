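# source: Toseland, C.P., McSparron, H., Davies, M.N., Flower, D.R. (2006) Nucleic Acids Res. 34, D199-D203 (transcribed)
group,pka
n_term,8.71
c_term,3.19
C,9.10
D,3.60
E,4.29
H,6.33
K,10.45
R,12.00
Y,9.61
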