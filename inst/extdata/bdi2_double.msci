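# two species, stacked double-BDI (14 parameters: 7 theta, 3 tau, 4 phi)
tree ((A,B)R;)
bdi X=A@0.00125 Y=B@0.00125
bdi Z=A@0.0025 W=B@0.0025
tau R=0.005
theta A=0.005 B=0.02 R=0.005 X=0.005 Y=0.02 Z=0.005 W=0.02
phi X=0.1 Y=0.2 Z=0.2 W=0.3
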