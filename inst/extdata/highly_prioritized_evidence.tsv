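gene	evidence
TRIOBP	NS,MX,SMR,DEPICT
USP36	NS,MX,SMR,DEPICT
LRIG1	NS,MX,SMR,DEPICT
PRR14	NS,MX,SMR,DEPICT
SENP2	NS,MX,SMR,DEPICT
PPL	NS,MX,SMR,DEPICT,SMR3
MLXIP	NS,MX,SMR,DEPICT
ITGA9	NS,MX,SMR,DEPICT,SMR3
YAF2	MX,SMR,DEPICT,SMR3
LNPEP	MX,SMR,DEPICT,SMR3
SLC39A1	MX,SMR,DEPICT,SMR3
MAPKAP1	MX,SMR,DEPICT,SMR3
TP53INP1	MX,SMR,DEPICT,SMR3
MAK16	NS,MX,SMR,SMR3
ERAP2	ML,MX,SMR,SMR3
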