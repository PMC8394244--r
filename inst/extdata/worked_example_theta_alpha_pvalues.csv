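channel,p
Fp1,0.0264
Fp2,0.0394
F7,0.4883
F3,0.5511
FZ,0.3612
F4,0.1582
F8,0.3105
T3,0.1352
C3,0.2859
CZ,0.8901
C4,0.5549
T4,0.2418
T5,0.0010
P3,0.0048
PZ,0.0207
P4,0.0036
T6,0.0002
O1,0.0028
O2,0.0035
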