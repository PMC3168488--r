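probe_id	F_SC	F_EPI	F_MES	F_LIV	F_MUS	F_KID	L_SC	L_EPI	L_MES	L_LIV	L_MUS	L_KID
Depdc6	1392	1506	947	791	888	263	10	11	14	18	12	12
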