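gene	S1	S2
GAPDH	120	80
COL1A1	30	260
PMEL	410	95
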