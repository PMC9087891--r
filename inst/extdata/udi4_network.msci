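# four species, two unidirectional introgression events (18 parameters:
# 11 theta, 5 tau, 2 phi)
tree (((A,B)S,C)T,D)R
udi H1=B@0.001 S1=C@0.001
udi H2=C@0.0015 S2=D@0.0015
tau R=0.004 T=0.0025 S=0.002
theta A=0.01 B=0.01 C=0.01 D=0.01 R=0.01 S=0.01 T=0.01 H1=0.01 S1=0.01 H2=0.01 S2=0.01
phi H1=0.1 H2=0.2
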