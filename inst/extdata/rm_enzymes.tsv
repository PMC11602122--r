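name	type	recognition	encoded_on
EcoAI	I	GAGNNNNNNNGTCA	chromosome
EcoBI	I	TGANNNNNNNNTGCT	chromosome
EcoKI	I	AACNNNNNNGTGC	chromosome
EcoR124I	I	GAANNNNNNRTCG	chromosome
EcoRI	II	GAATTC	plasmid
EcoRII	II	CCWGG	plasmid
EcoRV	II	GATATC	plasmid
EcoVIII	II	AAGCTT	plasmid
EcoP1	III	AGACC	plasmid
EcoP15	III	CAGCAG	plasmid
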