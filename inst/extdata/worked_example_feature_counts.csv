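band_spec,APEN,LZC,HFD,TSEN,DPS,DEEGA,ZCI,COH,total
theta/alpha,12,5,9,2,18,12,15,1,74
alpha/theta,12,7,0,2,17,15,15,0,68
alpha/delta,0,0,0,0,18,11,8,0,37
beta/theta,13,0,0,0,2,10,9,1,35
theta/beta,12,0,3,0,4,5,9,0,33
alpha,2,0,4,0,19,3,4,0,32
delta/alpha,1,0,0,0,18,4,7,0,30
delta,0,0,0,0,19,0,0,3,22
theta,0,0,0,0,18,0,0,3,19
theta/delta,0,0,0,0,17,0,0,0,18
delta/theta,8,0,0,1,0,4,4,0,17
gamma/theta,0,0,0,0,16,0,0,0,17
beta/delta,0,0,0,0,2,7,3,2,14
beta,2,0,4,0,1,1,3,2,13
theta/gamma,6,0,0,1,0,0,4,0,11
alpha/beta,0,4,0,0,4,0,0,0,8
gamma/delta,3,0,0,0,1,3,1,0,8
delta/beta,0,0,0,0,2,0,2,0,4
alpha/gamma,0,4,0,0,0,0,0,0,4
gamma,0,2,0,0,1,0,0,2,3
gamma/alpha,0,0,1,0,2,0,0,0,3
gamma/beta,0,1,0,0,1,0,0,0,3
beta/alpha,0,0,0,0,1,0,0,0,2
delta/gamma,0,0,0,0,0,0,0,0,0
beta/gamma,0,0,0,0,0,0,0,0,0
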