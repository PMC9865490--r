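ligand	receptor	source
TGFB1	TGFBR2	demo
WNT1	FZD9	demo
RSPO3	LGR4	demo
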