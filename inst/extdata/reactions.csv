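id,catalyst,equation,reversible,rate_law,km,keq,vmax_U_per_ml
Hex,Hex,Glc + ATP -> G6P + ADP,FALSE,irreversible_mm,Glc=0.12;ATP=0.2,NA,0.1
Pgi,Pgi,G6P -> F6P,TRUE,reversible_mm,G6P=1.4;F6P=0.3,0.31,10
Pfk,Pfk,F6P + ATP -> FBP + ADP,FALSE,irreversible_mm,F6P=0.1;ATP=0.1,NA,1
Fba,Fba,FBP -> DHAP + GAP,TRUE,reversible_mm,FBP=0.3;DHAP=2.0;GAP=2.4,0.069,5
Tpi,Tpi,DHAP -> GAP,TRUE,reversible_mm,DHAP=6.5;GAP=5.3,0.045,20
Gap,Gap,GAP + NAD + Pi -> BPG + NADH,TRUE,reversible_mm,GAP=0.21;NAD=0.09;Pi=2.0;BPG=0.05;NADH=0.06,0.05,6
mGap,mGap,GAP + NADP + Pi -> BPG + NADPH,TRUE,reversible_mm,GAP=0.25;NADP=0.09;Pi=2.0;BPG=0.05;NADPH=0.06,0.05,8
Pgk,Pgk,BPG + ADP -> PG3 + ATP,TRUE,reversible_mm,BPG=0.003;ADP=0.01;PG3=0.6;ATP=1.0,3200,2.5
Pgm,Pgm,PG3 -> PG2,TRUE,reversible_mm,PG3=1.2;PG2=0.08,0.19,15
Eno,Eno,PG2 -> PEP,TRUE,reversible_mm,PG2=0.04;PEP=0.5,6.7,15
Pyk,Pyk,PEP + ADP -> Pyr + ATP,FALSE,irreversible_mm,PEP=0.14;ADP=0.01,NA,2.5
Pdh,Pdh,Pyr + CoA + NAD -> AcCoA + NADH + CO2,FALSE,irreversible_mm,Pyr=2.5;CoA=0.5;NAD=0.3,NA,10
NoxE,NoxE,2 NADH + O2 -> 2 NAD + 2 H2O,FALSE,irreversible_mm,NADH=0.005,NA,25
PhaA,PhaA,2 AcCoA -> AcAcCoA + CoA,TRUE,reversible_mm,AcCoA=0.4;AcAcCoA=0.02;CoA=0.05,2e-4,10
Hmgs,Hmgs,AcAcCoA + AcCoA + H2O -> HMGCoA + CoA,FALSE,irreversible_mm,AcAcCoA=0.01;AcCoA=0.35,NA,15
Hmgr,Hmgr,HMGCoA + 2 NADPH -> Mev + CoA + 2 NADP,FALSE,irreversible_mm,HMGCoA=0.02;NADPH=0.05,NA,12
Mvk,Mvk,Mev + ATP -> MevP + ADP,FALSE,irreversible_mm,Mev=0.15;ATP=0.3,NA,0.12
Pmvk,Pmvk,MevP + ATP -> MevPP + ADP,FALSE,irreversible_mm,MevP=0.1;ATP=0.3,NA,0.12
Mdc,Mdc,MevPP + ATP -> IPP + ADP + Pi + CO2,FALSE,irreversible_mm,MevPP=0.05;ATP=0.3,NA,0.12
Idi,Idi,IPP -> DMAPP,TRUE,reversible_mm,IPP=0.1;DMAPP=0.1,1.0,4
Fpps,Fpps,IPP + DMAPP -> GPP + PPi,FALSE,irreversible_mm,IPP=0.02;DMAPP=0.02,NA,2
TS,TerpeneSynthase,GPP -> Terpene + PPi,FALSE,irreversible_mm,GPP=0.02,NA,1
PPase,PPase,PPi + H2O -> 2 Pi,FALSE,irreversible_mm,PPi=0.08,NA,10
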