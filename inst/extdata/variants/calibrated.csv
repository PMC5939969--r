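# source: IEF-calibrated terminal pKa values after Gauci et al. (2008); transcribed defaults, user-editable
context,residue,position,pka
n_term,default,,7.44
n_term,A,,7.58
n_term,M,,7.00
n_term,S,,6.86
n_term,P,,8.36
n_term,T,,6.96
n_term,V,,7.44
n_term,E,,7.70
n_term,G,,7.50
c_term,default,,3.55
sidechain,D,c-terminal,4.55
sidechain,E,c-terminal,4.75
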