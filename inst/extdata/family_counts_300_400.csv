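family,count
AF,2
AI,6
AL,1
AS,10
AU,2
AV,14
AW,2
CEP,3
DV,3
IL1,4
IL2,1
LU,2
OLQ,2
PD,1
PH,2
PV,5
RI,9
RM,7
SI,1
SM,4
UR,6
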