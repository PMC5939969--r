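# source: neighbor-effect constants after Cargile et al.; transcribed defaults, user-editable (ΔpKa applied to D/E sidechains and the C-terminus)
residue,offset,delta
K,-1,-0.24
K,1,-0.24
K,-2,-0.12
K,2,-0.12
K,-3,-0.06
K,3,-0.06
R,-1,-0.26
R,1,-0.26
R,-2,-0.13
R,2,-0.13
R,-3,-0.06
R,3,-0.06
H,-1,-0.10
H,1,-0.10
H,-2,-0.05
H,2,-0.05
D,-1,0.16
D,1,0.16
D,-2,0.08
D,2,0.08
E,-1,0.14
E,1,0.14
E,-2,0.07
E,2,0.07
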