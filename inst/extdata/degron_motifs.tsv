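motif_name	e3_ligase	pattern
APC_DBox	APC/C	RxxLxx[LIVM]
APC_KENBox	APC/C	xKENx
SCF_TrCP	SCF-beta-TrCP	DSGxx[ST]
MDM2_SWIB	MDM2	FxxxWxx[LIV]
KEAP1_Kelch	KEAP1	[DNS]x[ET]GE
SPOP_SBC	SPOP	[AVP]x[ST][ST][ST]
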