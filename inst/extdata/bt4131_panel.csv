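variant,substrate,kcat_km,sd,measured
WT,Glc6P,30.98,1.75,TRUE
WT,Fru6P,10.08,1.67,TRUE
WT,GlcN6P,2.08,0.48,TRUE
WT,GlcNAc6P,13.28,1.83,TRUE
M1,Glc6P,11.32,2.28,TRUE
M1,Fru6P,2.71,0.98,TRUE
M1,GlcN6P,19,3.7,TRUE
M1,GlcNAc6P,31.88,1.78,TRUE
M2,Glc6P,46.38,7.36,TRUE
M2,Fru6P,7.25,1.41,TRUE
M2,GlcN6P,26.39,1.49,TRUE
M2,GlcNAc6P,67.48,4.95,TRUE
M3,Glc6P,12.2,3.96,TRUE
M3,Fru6P,1.47,0.34,TRUE
M3,GlcN6P,2.09,0.48,TRUE
M3,GlcNAc6P,74.72,5.64,TRUE
M4,Glc6P,12.58,2.25,TRUE
M4,Fru6P,,,FALSE
M4,GlcN6P,,,FALSE
M4,GlcNAc6P,126.27,7.84,TRUE
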