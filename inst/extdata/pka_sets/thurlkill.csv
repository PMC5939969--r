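# source: Thurlkill, R.L. et al. (2006) Protein Sci. 15, 1214-1218 (transcribed)
group,pka
n_term,8.00
c_term,3.67
C,8.55
D,3.67
E,4.25
H,6.54
K,10.40
R,12.00
Y,9.84
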