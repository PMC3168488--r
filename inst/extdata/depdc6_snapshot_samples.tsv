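sample_id	line	tissue	diet	replicate
F_SC	F	SC	chow	1
F_EPI	F	EPI	chow	1
F_MES	F	MES	chow	1
F_LIV	F	LIV	chow	1
F_MUS	F	MUS	chow	1
F_KID	F	KID	chow	1
L_SC	L	SC	chow	1
L_EPI	L	EPI	chow	1
L_MES	L	MES	chow	1
L_LIV	L	LIV	chow	1
L_MUS	L	MUS	chow	1
L_KID	L	KID	chow	1
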