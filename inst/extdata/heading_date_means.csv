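trait,season,regime,mean
DH,S1,full,75.40
DH,S1,limited,74.04
DH,S2,full,75.71
DH,S2,limited,74.39
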