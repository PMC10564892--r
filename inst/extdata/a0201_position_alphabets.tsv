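position	amino_acids
P3	A,G,S,T,V,L,I,F,W,Y,P
P4	A,G,S,D,E,N,Q,K,P
P5	A,G,S,T,N,D,H,V,I,P
P6	A,G,S,T,V,L,I,M,F,Y,P
P7	A,G,S,T,V,L,R,K,P
P8	A,G,S,T,V,L,K,P
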