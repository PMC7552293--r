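breed,n_II,n_ID,n_DD
TS,894,13,0
LXBH,615,14,0
STHS,187,3,0
LFTS,48,1,0
HS,201,0,0
SS,48,0,0
AUW,326,0,0
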