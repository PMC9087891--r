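# five species, three BDI events all between sister lineages (8 towers)
tree (((A,B)S,(D,E)U)T,C)R
bdi X1=A@0.001 Y1=B@0.001
bdi X2=D@0.001 Y2=E@0.001
bdi X3=S@0.003 Y3=U@0.003
tau R=0.006 T=0.004 S=0.002 U=0.002
theta A=0.01 B=0.01 C=0.01 D=0.01 E=0.01 R=0.01 S=0.01 T=0.01 U=0.01 X1=0.005 Y1=0.02 X2=0.005 Y2=0.02 X3=0.005 Y3=0.02
phi X1=0.1 Y1=0.2 X2=0.1 Y2=0.2 X3=0.1 Y3=0.2
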