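name	recognition
BlnI	CCTAGG
AvrII	CCTAGG
EcoRI	GAATTC
BamHI	GGATCC
HindIII	AAGCTT
XbaI	TCTAGA
SpeI	ACTAGT
DdeI	CTNAG
HinfI	GANTC
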