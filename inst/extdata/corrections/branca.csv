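# source: neighbor-effect and carboxyl-count constants after Branca et al.; transcribed defaults, user-editable
kind,residue,offset,n_d,n_e,delta
neighbor,K,-1,,,-0.20
neighbor,K,1,,,-0.20
neighbor,K,-2,,,-0.10
neighbor,K,2,,,-0.10
neighbor,K,-3,,,-0.05
neighbor,K,3,,,-0.05
neighbor,K,-4,,,-0.03
neighbor,K,4,,,-0.03
neighbor,K,-5,,,-0.02
neighbor,K,5,,,-0.02
neighbor,K,-6,,,-0.01
neighbor,K,6,,,-0.01
neighbor,R,-1,,,-0.22
neighbor,R,1,,,-0.22
neighbor,R,-2,,,-0.11
neighbor,R,2,,,-0.11
neighbor,R,-3,,,-0.06
neighbor,R,3,,,-0.06
neighbor,R,-4,,,-0.03
neighbor,R,4,,,-0.03
neighbor,R,-5,,,-0.02
neighbor,R,5,,,-0.02
neighbor,R,-6,,,-0.01
neighbor,R,6,,,-0.01
neighbor,H,-1,,,-0.08
neighbor,H,1,,,-0.08
neighbor,H,-2,,,-0.04
neighbor,H,2,,,-0.04
neighbor,D,-1,,,0.14
neighbor,D,1,,,0.14
neighbor,D,-2,,,0.07
neighbor,D,2,,,0.07
neighbor,D,-3,,,0.03
neighbor,D,3,,,0.03
neighbor,E,-1,,,0.12
neighbor,E,1,,,0.12
neighbor,E,-2,,,0.06
neighbor,E,2,,,0.06
neighbor,E,-3,,,0.03
neighbor,E,3,,,0.03
carboxyl,,,1,0,0.05
carboxyl,,,2,0,0.10
carboxyl,,,3,0,0.15
carboxyl,,,0,1,0.03
carboxyl,,,0,2,0.06
carboxyl,,,0,3,0.09
carboxyl,,,1,1,0.08
carboxyl,,,1,2,0.11
carboxyl,,,2,1,0.13
carboxyl,,,2,2,0.16
carboxyl,,,3,1,0.18
carboxyl,,,1,3,0.14
carboxyl,,,3,2,0.21
carboxyl,,,2,3,0.19
carboxyl,,,3,3,0.24
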