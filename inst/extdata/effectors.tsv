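# stage: example effector catalogue (illustrative values, synthetic)
# columns: name	total_conc_nM	kd_nM	pathway
name	total_conc_nM	kd_nM	pathway
RAF	300	50	RAF/MAPK
RAL	200	1500	RAL
PI3K	150	300	PI3K
TIAM	100	4000	TIAM
AFDN	120	2500	AFDN
PLCE	80	8000	PLCE
RIN1	90	120	RIN1
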