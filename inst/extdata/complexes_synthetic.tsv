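# stage: synthetic example complex definitions
# columns: complex	member
complex	member
CCT_like	PREY00001
CCT_like	PREY00002
CCT_like	PREY00003
CCT_like	PREY00004
PP2A_like	PREY00005
PP2A_like	PREY00006
PP2A_like	PREY00007
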