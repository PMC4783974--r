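locus	status	maf	he	fis
acss3	failed	NA	NA	NA
fbxo32	failed	NA	NA	NA
fgf6b	monomorphic	NA	NA	NA
ghr2	monomorphic	NA	NA	NA
got1a	monomorphic	NA	NA	NA
myod	monomorphic	NA	NA	NA
actc	polymorphic	0.368	0.471	-0.06
akirin2	polymorphic	0.324	0.445	0.074
akt3	polymorphic	0.118	0.21	-0.119
atp2a1	polymorphic	0.485	0.507	0.014
chpt1	polymorphic	0.338	0.453	-0.234
eno1	polymorphic	0.25	0.381	-0.005
far2	polymorphic	0.088	0.163	-0.082
foxm1	polymorphic	0.344	0.461	0.322
foxo1b	polymorphic	0.353	0.463	-0.015
igf1	polymorphic	0.029	0.058	-0.015
igf2b	polymorphic	0.265	0.395	-0.043
igfbp2	polymorphic	0.324	0.445	0.074
igfbp3	polymorphic	0.103	0.187	-0.1
insrb	polymorphic	0.132	0.233	-0.138
jak2a	polymorphic	0.441	0.501	0.06
jak2b	polymorphic	0.044	0.086	-0.031
lepr	polymorphic	0.5	0.508	0.074
lum	polymorphic	0.029	0.058	-0.015
mef2a	polymorphic	0.044	0.086	-0.031
mir133b	polymorphic	0.059	0.112	-0.048
mstn1	polymorphic	0.176	0.296	0.205
mtor	polymorphic	0.103	0.187	-0.1
myog	polymorphic	0.059	0.112	-0.048
pah	polymorphic	0.162	0.275	0.039
pklr	polymorphic	0.029	0.058	-0.015
pkm	polymorphic	0.439	0.501	0.093
ptn	polymorphic	0.25	0.379	-0.32
pvalb1	polymorphic	0.044	0.086	-0.031
smad4b	polymorphic	0.074	0.138	-0.065
sox5	polymorphic	0.426	0.496	-0.128
ssr3	polymorphic	0.176	0.295	0.003
stats5.1	polymorphic	0.309	0.434	0.119
tgfb1	polymorphic	0.426	0.496	-0.007
tgfb2	polymorphic	0.132	0.233	-0.138
tgfbr1	polymorphic	0.029	0.058	-0.015
tgfbr2	polymorphic	0.235	0.365	-0.13
tgfbr3	polymorphic	0.338	0.454	-0.102
tnnc2	polymorphic	0.368	0.471	-0.06
usp18	polymorphic	0.191	0.313	-0.222
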