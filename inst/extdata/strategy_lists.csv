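label,cell
NP,ADF
NP,ASI
NP,AUA
NP,AVA
NP,AVB
NP,AVD
NP,AVE
NP,DVA
NP,DVC
NP,IL2D
NP,IL2L/R
NP,IL2V
NP,PVP
NP,PVR
NP,RIA
NP,RIB
NP,RIG
NP,RIH
NP,RIR
NP,URB
NP,URYD
NP,URYV
XOR_FIRST,ALM
XOR_FIRST,BDU
XOR_FIRST,DVC
XOR_FIRST,IL2D
XOR_SECOND,AVA
XOR_SECOND,AVB
XOR_SECOND,AVD
XOR_SECOND,AVE
XOR_SECOND,AWB
XOR_SECOND,BAG
XOR_SECOND,IL2L/R
XOR_SECOND,RIA
XOR_SECOND,URYD
XOR_SECOND,URYV
XNOR,ADF
XNOR,ASI
XNOR,DVA
XNOR,IL2V
XNOR,PVR
XNOR,PVT
XNOR,SAAD
XNOR,SAAV
PN,ADA
PN,ADL
PN,AFD
PN,AIA
PN,AIB
PN,AIN
PN,AIY
PN,AIZ
PN,ASE
PN,ASG
PN,ASH
PN,ASJ
PN,ASK
PN,AWA
PN,AWC
PN,FLP
PN,OLL
PN,OLQD
PN,OLQV
PN,PVC
PN,RIF
PN,RIM
PN,RIP
PN,URX
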