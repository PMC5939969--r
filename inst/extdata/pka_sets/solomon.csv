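# source: Solomon, T.W.G. (1998) Fundamentals of Organic Chemistry, 5th ed. (transcribed)
group,pka
n_term,9.60
c_term,2.40
C,8.30
D,3.90
E,4.30
H,6.00
K,10.50
R,12.50
Y,10.10
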