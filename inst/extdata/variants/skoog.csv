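# source: Skoog, B., Wichman, A. (1986) Trends Anal. Chem. 5, 82-83; flat terminal pKas (transcribed)
context,residue,position,pka
n_term,default,,8.60
c_term,default,,3.60
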