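# three species, two nonsister BDI events: four unidentifiable models
tree (A,(B,C)S)R
bdi X=B@0.001 Y=C@0.001
bdi Z=A@0.002 W=X@0.002
tau R=0.004 S=0.003
theta A=0.01 B=0.01 C=0.01 R=0.01 S=0.01 X=0.005 Y=0.02 Z=0.005 W=0.02
phi X=0.1 Y=0.2 Z=0.2 W=0.3
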