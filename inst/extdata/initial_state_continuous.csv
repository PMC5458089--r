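species,concentration_mM
Glc,500
Pi,20
FBP,1
ATP,4
NADP,1.5
NAD,0.2
CoA,1.5
O2,0.25
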