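allotype	supertype
A*01:01	A01
A*02:01	A02
A*02:06	A02
A*03:01	A03
A*11:01	A03
A*24:02	A24
A*68:01	A02
A*68:02	A02
B*07:02	B07
B*08:01	B08
B*15:01	B62
B*27:05	B27
B*27:09	B27
B*35:01	B07
B*44:02	B44
B*57:01	B58
B*58:01	B58
E*01:03	HLA-E
G*01:01	HLA-G
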