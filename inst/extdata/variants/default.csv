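# source: Bjellqvist, B. et al. (1993) Electrophoresis 14, 1023-1031; residue-dependent terminal pKa table (transcribed)
context,residue,position,pka
n_term,default,,7.50
n_term,A,,7.59
n_term,M,,7.00
n_term,S,,6.93
n_term,P,,8.36
n_term,T,,6.82
n_term,V,,7.44
n_term,E,,7.70
c_term,default,,3.55
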