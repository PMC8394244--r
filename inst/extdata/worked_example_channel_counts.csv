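channel,APEN,LZC,HFD,TSEN,DPS,DEEGA,ZCI,total
P4,7,5,4,0,10,10,12,48
P3,9,2,4,0,9,8,13,45
PZ,8,2,3,2,11,9,10,45
T6,3,6,2,2,9,7,7,36
T5,2,3,4,2,9,6,7,33
C4,6,0,0,0,11,6,4,27
T4,4,2,1,0,8,7,3,25
T3,4,0,1,0,14,3,2,24
C3,4,0,0,0,12,4,4,24
CZ,6,0,0,0,9,3,6,24
O2,3,3,1,0,10,3,4,24
O1,4,0,1,0,8,3,4,20
F8,2,0,0,0,12,1,2,17
F7,3,0,0,0,9,2,2,16
F3,3,0,0,0,9,1,2,15
FZ,3,0,0,0,7,2,2,14
Fp1,0,0,0,0,9,0,0,9
F4,0,0,0,0,9,0,0,9
Fp2,0,0,0,0,6,0,0,6
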