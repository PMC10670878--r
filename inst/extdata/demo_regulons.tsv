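protein_id	regulons
CitZ	SigA
Icd	SigA
OdhB	SigA
RpsB	SigA
SpoIIQ	SigF
SspB	SigF
Gpr	SigF
SleB	SigG
SspA	SigG
PdaA	SigG
SpoIIIAA	SigE
SpoIIIAH	SigE
SpoIVA	SigE
GerM	SigE
CotA	SigK
CotB	SigK
GerE	SigK
SpoVK	SigE,SigK
RocA	SigA,SigE
AhpC	SigA,SigH
Spo0F	SigH,Spo0A
KinA	SigH
YabP	SigE,SigF
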