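id,name,carbon,phosphate,adenine,nicotinamide_nad,nicotinamide_nadp,coenzyme_a,constant
Glc,glucose,6,0,0,0,0,0,FALSE
G6P,glucose 6-phosphate,6,1,0,0,0,0,FALSE
F6P,fructose 6-phosphate,6,1,0,0,0,0,FALSE
FBP,fructose 1;6-bisphosphate,6,2,0,0,0,0,FALSE
DHAP,dihydroxyacetone phosphate,3,1,0,0,0,0,FALSE
GAP,glyceraldehyde 3-phosphate,3,1,0,0,0,0,FALSE
BPG,1;3-bisphosphoglycerate,3,2,0,0,0,0,FALSE
PG3,3-phosphoglycerate,3,1,0,0,0,0,FALSE
PG2,2-phosphoglycerate,3,1,0,0,0,0,FALSE
PEP,phosphoenolpyruvate,3,1,0,0,0,0,FALSE
Pyr,pyruvate,3,0,0,0,0,0,FALSE
AcCoA,acetyl-CoA,2,0,0,0,0,1,FALSE
AcAcCoA,acetoacetyl-CoA,4,0,0,0,0,1,FALSE
HMGCoA,3-hydroxy-3-methylglutaryl-CoA,6,0,0,0,0,1,FALSE
Mev,mevalonate,6,0,0,0,0,0,FALSE
MevP,mevalonate 5-phosphate,6,1,0,0,0,0,FALSE
MevPP,mevalonate 5-pyrophosphate,6,2,0,0,0,0,FALSE
IPP,isopentenyl pyrophosphate,5,2,0,0,0,0,FALSE
DMAPP,dimethylallyl pyrophosphate,5,2,0,0,0,0,FALSE
GPP,geranyl pyrophosphate,10,2,0,0,0,0,FALSE
Terpene,monoterpene product,10,0,0,0,0,0,FALSE
ATP,ATP,0,3,1,0,0,0,FALSE
ADP,ADP,0,2,1,0,0,0,FALSE
NAD,NAD+,0,0,0,1,0,0,FALSE
NADH,NADH,0,0,0,1,0,0,FALSE
NADP,NADP+,0,0,0,0,1,0,FALSE
NADPH,NADPH,0,0,0,0,1,0,FALSE
CoA,coenzyme A,0,0,0,0,0,1,FALSE
Pi,inorganic phosphate,0,1,0,0,0,0,FALSE
PPi,inorganic pyrophosphate,0,2,0,0,0,0,FALSE
CO2,carbon dioxide,1,0,0,0,0,0,FALSE
O2,dissolved oxygen,0,0,0,0,0,0,TRUE
H2O,water,0,0,0,0,0,0,TRUE
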