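pair,count
F4-F8,3
FZ-F8,2
T3-T4,2
Fp2-F4,1
F4-T3,1
F4-T4,1
F8-P4,1
T3-P4,1
T3-T6,1
T4-P3,1
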