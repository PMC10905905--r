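CCC1COCC1
CCOCB(O)O
Cc1cscc1
CCOCC#N
Brc1cocc1
CCC1CCCCC1
BrC1CCCCC1
NCc1cocc1
FC(C1CCCCC1)(F)F
OB(C1COCC1)O
Oc1cccc(c1)Br
NCc1ccccc1CN
OC(=O)c1cocc1
FC(c1cocc1)(F)F
Oc1ncccc1C(F)(F)F
N#Cc1cocc1
Fc1ccccn1
OB(C1CCCCC1)O
FC(c1ccccc1)(F)F
CCCO
CCC1CCCC1S
COc1cccnc1Br
Brc1cccnc1F
CC(CN)COC
CCOCC
CCNC(=O)B(O)O
N#Cc1cccnc1Br
CCOCBr
C=CC1COCC1
BrC1COCC1
OC(=O)N1CCCC1
Nc1ccccc1Cl
CCNC(=O)F
COc1cccc(c1)N
CCNC(=O)C(=O)O
CCCCl
CCNC(=O)C
Sc1ccccc1Br
CC(C(=O)O)CC=C
ClC1CCCCC1
COC1CCCC1Br
OB(c1cocc1)O
Oc1cocc1
CCNC=O
SN1CCCC1
CC(Cl)C
c1ccccc1
OB(c1ccccc1)O
N#CC1CCCC1
COC1CCCCC1
CON1CCCC1
CCCC(F)(F)F
OC1CCCCC1
FCC(B(O)O)C
CCC1CCCC1C
NCc1ccccc1S
Nc1ccccc1C(F)(F)F
NCc1cscc1
NCc1ccccc1O
Cc1ccccc1Br
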