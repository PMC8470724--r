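name	polarity	charge	mass_shift	multiplier
M+H	positive	1	 1.00727646688	1
M+Na	positive	1	22.98922070099	1
M+K	positive	1	38.96315790649	1
M+NH4	positive	1	18.03382555317	1
M-H	negative	1	-1.00727646688	1
M+Cl	negative	1	34.96940128991	1
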