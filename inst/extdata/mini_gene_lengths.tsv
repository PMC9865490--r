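gene	length_kb
GAPDH	1.4
COL1A1	5.9
PMEL	2.1
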