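# two species, one BDI pair between the sister lineages (9 parameters)
tree ((A,B)R;)
bdi X=A@0.00125 Y=B@0.00125
tau R=0.01
theta A=0.01 B=0.01 R=0.01 X=0.005 Y=0.02
phi X=0.7 Y=0.2
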